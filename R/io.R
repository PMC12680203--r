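#' Read a labelled table from CSV or ARFF
#'
#' CSV files need a header row; attribute columns are parsed as doubles and
#' the class column as character, preserving row order. ARFF files are read
#' with \code{foreign::read.arff}, so numeric and nominal attributes behave
#' as declared (nominal labels keep their declaration order as factor
#' levels).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, or `"arff"`.
#' @param class Name of the class column; must exist.
#' @return A tibble.
#' @export
read_table <- function(path, format = c("auto", "csv", "arff"),
                       class = "class") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  out <- if (format == "arff") {
    as_tibble(foreign::read.arff(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (!class %in% names(out)) {
    abort(sprintf("Class column '%s' not found in %s.", class, path))
  }
  bad <- purrr::imap(out[setdiff(names(out), class)], function(v, nm) {
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      row <- which(is.na(conv) & !is.na(v))
      if (length(row)) {
        abort(sprintf("Unparseable numeric cell at row %d, column '%s': '%s'.",
                      row[1], nm, v[row[1]]))
      }
    }
    NULL
  })
  out[[class]] <- as.character(out[[class]])
  out
}

#' Write a labelled table
#'
#' @param data Data frame.
#' @param path Destination; extension chooses the format under `"auto"`.
#' @param format `"auto"`, `"csv"`, or `"arff"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(data, path, format = c("auto", "csv", "arff")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  if (format == "arff") {
    foreign::write.arff(as.data.frame(data), path)
  } else {
    readr::write_csv(data, path, progress = FALSE)
  }
  invisible(path)
}

#' Serialize an MDEM model to JSON
#'
#' Writes everything needed to resume evolution exactly: class labels in
#' order, moment order, weighting mode, per-class counts and full powered
#' sums at maximum numeric precision. [mdem_from_json()] reconstructs a model
#' whose predictions are bit-identical to the original's.
#'
#' @param model A fitted [mdem()] model.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
mdem_to_json <- function(model, path = NULL) {
  payload <- list(
    format = "mdem-model",
    version = 1L,
    classes = model$classes,
    order = model$order,
    evolve = model$evolve,
    weight = model$weight,
    class_col = model$class_col,
    attr_names = as.list(model$attr_names),
    n_train = model$n_train,
    states = lapply(model$states, function(st) {
      list(count = st$count, l_max = st$l_max,
           powered_sums = st$powered_sums) # row l, column k
    })
  )
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' @rdname mdem_to_json
#' @param json A path to, or the text of, JSON written by [mdem_to_json()].
#' @export
mdem_from_json <- function(json) {
  p <- jsonlite::fromJSON(json, simplifyMatrix = TRUE)
  if (!identical(p$format, "mdem-model")) abort("Not an MDEM model JSON payload.")
  attr_names <- unlist(p$attr_names)
  states <- purrr::map(p$classes, function(cl) {
    raw <- p$states[[cl]]
    ps <- matrix(as.numeric(raw$powered_sums), nrow = raw$l_max)
    st <- moment_state(ncol(ps), order = p$order, l_max = raw$l_max,
                       attr_names = attr_names)
    st$count <- as.integer(raw$count)
    st$powered_sums <- ps
    st$mean <- ps[1L, ] / st$count
    st$central_moment <- derive_moments(st, p$order)
    st
  })
  names(states) <- p$classes
  structure(
    list(classes = p$classes, states = states, order = as.integer(p$order),
         evolve = isTRUE(p$evolve), weight = p$weight,
         class_col = p$class_col, attr_names = attr_names,
         n_train = as.integer(p$n_train)),
    class = "mdem"
  )
}
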
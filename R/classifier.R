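#' Fit a minimum-displacement-in-existing-moment (MDEM) classifier
#'
#' MDEM summarises each class by the order-`n` central moment vector of its
#' attributes (the mean itself for `order = 1`). A test point is temporarily
#' included in every class, the Euclidean distance between each class's
#' existing and would-be moment vector is computed, multiplied by the class's
#' cardinality — without that weight a large class swallows every point,
#' because a single inclusion moves its moments by only O(1/(N+1)) — and the
#' point is assigned to the class with the smallest weighted displacement.
#'
#' Training is a single pass over the rows accumulating per-class powered sums,
#' so it is linear in the number of rows; each prediction touches only the
#' per-class sufficient statistics and so costs the same no matter how many
#' points have been absorbed.
#'
#' @param data A data frame of numeric attributes plus one class column.
#' @param class Name of the class column (string or bare name). Default
#'   `"class"`.
#' @param order Moment order used for scoring: 1 compares class means,
#'   2 variances, 3 and 4 the third and fourth central moments.
#' @param evolve If `TRUE` (the default), each predicted point is committed to
#'   its chosen class so the model keeps learning during testing; if `FALSE`
#'   the model stays frozen and predictions are a pure function of the fitted
#'   model and the point.
#' @param weight Cardinality weight used on raw displacements: the class's
#'   current count (`"count"`, the default) or `"count_plus_1"`, the size the
#'   class would have after inclusion.
#' @param l_max Highest powered sum maintained per class.
#'
#' @return An object of class `mdem`: the ordered class labels, one
#'   [moment_state()] per class, and the scoring settings.
#' @examples
#' d <- worked_example()
#' fit <- mdem(d, class = "class", order = 3)
#' tidy(fit)
#' @export
mdem <- function(data, class = "class", order = 1L, evolve = TRUE,
                 weight = c("count", "count_plus_1"), l_max = max(order, 4L)) {
  weight <- match.arg(weight)
  class_col <- resolve_class_col(data, {{ class }})
  labels <- data[[class_col]]
  if (anyNA(labels)) abort("Class labels must not be missing.")
  labels <- as.character(labels)
  x <- as.matrix(data[setdiff(names(data), class_col)])
  if (!is.numeric(x)) abort("All attribute columns must be numeric.")
  if (any(!is.finite(x))) abort("All attribute values must be finite (impute/filter first).")
  if (nrow(x) < 1L) abort("Cannot fit on zero rows.")
  classes <- unique(labels)
  if (is.factor(data[[class_col]])) {
    lev <- levels(data[[class_col]])
    present <- lev %in% labels
    if (!all(present)) {
      abort(sprintf("Declared class(es) with no training rows: %s.",
                    paste(lev[!present], collapse = ", ")))
    }
    classes <- lev
  }
  d <- ncol(x)
  states <- lapply(classes, function(cl) {
    rows <- x[labels == cl, , drop = FALSE]
    st <- moment_state(d, order = order, l_max = l_max,
                       attr_names = colnames(x))
    ## one-pass accumulation of all powered sums for the class
    st$count <- nrow(rows)
    for (l in seq_len(st$l_max)) st$powered_sums[l, ] <- colSums(rows^l)
    st$mean <- st$powered_sums[1L, ] / st$count
    st$central_moment <- derive_moments(st, order)
    st
  })
  names(states) <- classes
  structure(
    list(
      classes = classes,
      states = states,
      order = as.integer(order),
      evolve = isTRUE(evolve),
      weight = weight,
      class_col = class_col,
      attr_names = colnames(x),
      n_train = nrow(x)
    ),
    class = "mdem"
  )
}

resolve_class_col <- function(data, class) {
  q <- enquo(class)
  nm <- tryCatch(rlang::eval_tidy(q), error = function(e) NULL)
  nm <- if (is.character(nm)) nm else as_name(q)
  if (!nm %in% names(data)) {
    abort(sprintf("Class column '%s' not found in the data.", nm))
  }
  nm
}

#' @export
print.mdem <- function(x, ...) {
  cat("MDEM classifier (order", x$order,
      if (x$order == 1) "= mean)" else "central moment)",
      if (x$evolve) "[evolving]" else "[frozen]", "\n")
  cat("  classes:", paste0(x$classes, " (n=",
                           vapply(x$states, `[[`, 0L, "count"), ")",
                           collapse = ", "), "\n")
  cat("  attributes:", length(x$attr_names), "\n")
  invisible(x)
}

## moment vector the classifier compares: mean for order 1, mu_n otherwise
scoring_vector <- function(state, order) {
  if (order == 1L) state$mean else state$central_moment
}

#' Per-class displacement scores for one point
#'
#' Pseudo-includes `x` in every class (no state is modified), computes the
#' Euclidean distance between each class's existing and temporary scoring
#' vector, weights it by class cardinality, and identifies the argmin class.
#' Ties are broken in favour of the earliest class in declaration order.
#'
#' @param model A fitted [mdem()] model.
#' @param x Numeric attribute vector (or 1-row data frame of attributes).
#' @return A tibble with one row per class: `class`, `count`, `raw`,
#'   `weighted`, `chosen`, plus attribute `margin` (the gap between the two
#'   smallest weighted displacements; see [mdem_margin()]).
#' @export
mdem_displacement <- function(model, x) {
  x <- as_point(model, x)
  raw <- unname(vapply(model$states, function(st) {
    tmp <- absorb_point(st, x)
    sqrt(sum((scoring_vector(tmp, model$order) -
                scoring_vector(st, model$order))^2))
  }, 0))
  counts <- unname(vapply(model$states, `[[`, 0L, "count"))
  w <- if (model$weight == "count") counts else counts + 1
  weighted <- raw * w
  chosen <- which.min(weighted) # first index wins ties
  margin <- if (length(weighted) >= 2) {
    s <- sort(weighted)
    s[2] - s[1]
  } else {
    NA_real_
  }
  out <- tibble(
    class = model$classes,
    count = counts,
    raw = raw,
    weighted = weighted,
    chosen = seq_along(weighted) == chosen
  )
  attr(out, "margin") <- margin
  class(out) <- c("mdem_displacement", class(out))
  out
}

as_point <- function(model, x) {
  if (is.data.frame(x)) {
    x <- as.matrix(x[intersect(names(x), model$attr_names)])
    if (nrow(x) != 1L) abort("Expected a single point.")
    x <- drop(x)
  }
  d <- length(model$attr_names)
  if (length(x) != d) {
    abort(sprintf("Attribute dimension mismatch: model has %d attribute(s), point has %d.",
                  d, length(x)))
  }
  as.numeric(x)
}

#' Classification margin of a point
#'
#' The empirical margin is the gap between the smallest and second-smallest
#' cardinality-weighted displacement. A positive margin means the winning
#' class is unique; the larger it is, the more estimation error in the class
#' displacements the decision can absorb before flipping (an error bounded by
#' half the margin can never change the argmin).
#'
#' @inheritParams mdem_displacement
#' @return A single non-negative number.
#' @export
mdem_margin <- function(model, x) {
  if (length(model$classes) < 2L) {
    abort("Margin is undefined for a single-class model.")
  }
  attr(mdem_displacement(model, x), "margin")
}

#' Predict with an MDEM model
#'
#' Applies the displacement rule to each row of `new_data` in order. With
#' `evolve = TRUE` each prediction commits the point to its winning class
#' before the next row is scored, so results can depend on row order (that is
#' the model's online-learning contract); with `evolve = FALSE` the model is
#' frozen and the output is invariant to any permutation of the rows. The
#' evolved model is available via [mdem_evolve()] when you need to keep it.
#'
#' @param object A fitted [mdem()] model.
#' @param new_data Data frame containing the model's attribute columns (a
#'   class column, if present, is ignored).
#' @param evolve Override the model's evolve flag for this call.
#' @param ... Unused.
#' @return Character vector of predicted class labels, one per row.
#' @export
predict.mdem <- function(object, new_data, evolve = NULL, ...) {
  mdem_evolve(object, new_data, evolve = evolve)$class
}

#' Predict and return the evolved model
#'
#' Same sequential rule as [predict.mdem()], but returns both the predicted
#' labels and the model as it stands after any commits — the entry point for
#' resuming online evolution across batches.
#'
#' @inheritParams predict.mdem
#' @param model A fitted [mdem()] model.
#' @return A list with elements `class` (character labels) and `model`.
#' @export
mdem_evolve <- function(model, new_data, evolve = NULL) {
  evolve <- if (is.null(evolve)) model$evolve else isTRUE(evolve)
  xm <- as.matrix(new_data[intersect(names(new_data), model$attr_names)])
  if (ncol(xm) != length(model$attr_names)) {
    abort(sprintf("new_data must contain the %d attribute column(s) the model was fitted on.",
                  length(model$attr_names)))
  }
  n <- nrow(xm)
  out <- character(n)
  for (i in seq_len(n)) {
    sc <- mdem_displacement(model, xm[i, ])
    j <- which(sc$chosen)
    out[i] <- model$classes[j]
    if (evolve) {
      model$states[[j]] <- absorb_point(model$states[[j]], xm[i, ])
    }
  }
  list(class = out, model = model)
}

#' @method tidy mdem
#' @export
tidy.mdem <- function(x, ...) {
  purrr::map_dfr(x$classes, function(cl) {
    st <- x$states[[cl]]
    tibble(
      class = cl,
      attribute = attr_labels(st$attr_names, ncol(st$powered_sums)),
      count = st$count,
      mean = st$mean,
      central_moment = st$central_moment
    )
  })
}

#' @method glance mdem
#' @export
glance.mdem <- function(x, ...) {
  tibble(
    n_classes = length(x$classes),
    n_attributes = length(x$attr_names),
    order = x$order,
    evolve = x$evolve,
    n_absorbed = sum(vapply(x$states, `[[`, 0L, "count")),
    n_train = x$n_train
  )
}

#' @method autoplot mdem_displacement
#' @export
autoplot.mdem_displacement <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object), c("raw", "weighted"),
    names_to = "kind", values_to = "displacement"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$displacement,
                                   fill = .data$chosen)) +
    ggplot2::geom_col(show.legend = c(fill = TRUE)) +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = "class", y = "moment displacement",
                  fill = "chosen") +
    ggplot2::theme_minimal()
}
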
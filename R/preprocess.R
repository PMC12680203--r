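#' Mean imputation of missing values
#'
#' Replaces missing cells in numeric attribute columns by the mean of the
#' column's non-missing values. `NA` always counts as missing; in clinical
#' tables a physiologically impossible sentinel (typically a coded 0, e.g. a
#' zero serum-insulin or blood-pressure reading) can additionally be declared
#' missing per column via `sentinels`.
#'
#' @param data A data frame.
#' @param sentinels Named numeric vector (or list) mapping column names to the
#'   sentinel value that marks a missing cell in that column, e.g.
#'   `c(glucose = 0, insulin = 0)`.
#' @param class Class column to leave untouched (ignored if absent).
#' @return The imputed tibble, carrying the preprocessing report in its
#'   `report` attribute (see [preprocess_report()]).
#' @export
impute_missing <- function(data, sentinels = NULL, class = "class") {
  out <- as_tibble(data)
  cols <- attr_columns(out, class)
  counts <- setNames(integer(length(cols)), cols)
  for (cl in cols) {
    v <- out[[cl]]
    miss <- is.na(v)
    if (!is.null(sentinels) && cl %in% names(sentinels)) {
      miss <- miss | (v == sentinels[[cl]] & !is.na(v))
    }
    if (all(miss)) {
      abort(sprintf("Column '%s' has no non-missing values to impute from.", cl))
    }
    if (any(miss)) v[miss] <- mean(v[!miss])
    counts[cl] <- sum(miss)
    out[[cl]] <- v
  }
  add_report(out, data, list(imputed = counts))
}

#' Interquartile-range outlier and extreme-value row filter
#'
#' Per attribute, computes the quartiles Q1 and Q3 and the fences
#' `[Q1 - f*IQR, Q3 + f*IQR]` for the outlier factor and the (wider) extreme
#' factor. A row is dropped if any attribute falls outside its outlier fence;
#' the report tallies dropped rows by their worst flag (extreme beats
#' outlier). With both factors infinite nothing is removed.
#'
#' @inheritParams impute_missing
#' @param outlier_factor,extreme_factor IQR multipliers for the two fences;
#'   `outlier_factor <= extreme_factor`. Defaults 3 and 6, the conventional
#'   defaults of this filter family.
#' @param quantile_type Quantile estimator passed to [stats::quantile()];
#'   default 7 (linear interpolation between order statistics). Other tools'
#'   quartile rules differ, so row counts need not match theirs exactly.
#' @return The filtered tibble (a subset of the input rows, order preserved),
#'   with the report attached.
#' @export
iqr_filter <- function(data, outlier_factor = 3, extreme_factor = 6,
                       class = "class", quantile_type = 7) {
  if (outlier_factor > extreme_factor) {
    abort("outlier_factor must not exceed extreme_factor.")
  }
  out <- as_tibble(data)
  if (nrow(out) < 4L) abort("IQR filtering needs at least 4 rows for stable quartiles.")
  cols <- attr_columns(out, class)
  flag_out <- flag_ext <- rep(FALSE, nrow(out))
  for (cl in cols) {
    v <- out[[cl]]
    qs <- quantile(v, c(0.25, 0.75), na.rm = TRUE, type = quantile_type,
                   names = FALSE)
    iqr <- qs[2] - qs[1]
    lo_o <- qs[1] - outlier_factor * iqr
    hi_o <- qs[2] + outlier_factor * iqr
    lo_e <- qs[1] - extreme_factor * iqr
    hi_e <- qs[2] + extreme_factor * iqr
    flag_out <- flag_out | (!is.na(v) & (v < lo_o | v > hi_o))
    flag_ext <- flag_ext | (!is.na(v) & (v < lo_e | v > hi_e))
  }
  n_ext <- sum(flag_ext)
  n_out <- sum(flag_out & !flag_ext)
  kept <- out[!flag_out, , drop = FALSE]
  add_report(kept, data, list(
    outlier_rows = n_out,
    extreme_rows = n_ext,
    rows_in = nrow(out),
    rows_out = nrow(kept)
  ))
}

#' Min-max scaling to \[0, 1\]
#'
#' Maps every attribute by `(x - min) / (max - min)`. Constant attributes map
#' to 0. The observed `(min, max)` per attribute are recorded in the report
#' and can be reused (via `params`) to place new data on the training scale.
#'
#' @inheritParams impute_missing
#' @param params Optional scaling parameters (tibble with `attribute`, `min`,
#'   `max`, as found in a previous report) to apply instead of the observed
#'   range.
#' @return The scaled tibble with the report attached.
#' @export
minmax_scale <- function(data, params = NULL, class = "class") {
  out <- as_tibble(data)
  cols <- attr_columns(out, class)
  if (is.null(params)) {
    params <- tibble(
      attribute = cols,
      min = vapply(cols, function(cl) min(out[[cl]], na.rm = TRUE), 0,
                   USE.NAMES = FALSE),
      max = vapply(cols, function(cl) max(out[[cl]], na.rm = TRUE), 0,
                   USE.NAMES = FALSE)
    )
  }
  for (cl in cols) {
    p <- params[params$attribute == cl, ]
    if (nrow(p) != 1L) abort(sprintf("No scaling parameters for column '%s'.", cl))
    rng <- p$max - p$min
    out[[cl]] <- if (rng > 0) (out[[cl]] - p$min) / rng else rep(0, nrow(out))
  }
  add_report(out, data, list(scaling = params))
}

#' Full preprocessing pipeline
#'
#' Applies, in order: mean imputation of missing/sentinel cells,
#' IQR outlier and extreme-value row removal, and min-max scaling to \[0, 1\].
#' That ordering matters — imputation must see raw (unscaled) columns, and
#' scaling must see the post-filter range. By default the scaling range is
#' computed on the full dataset before any cross-validation split; this
#' mirrors the whole-dataset filtering workflow common in applied work and
#' leaks (only) the per-attribute range across folds — pass previously
#' recorded `params` to [minmax_scale()] for strict per-fold scaling.
#'
#' @inheritParams impute_missing
#' @inheritParams iqr_filter
#' @return The processed tibble with the cumulative report attached.
#' @examples
#' d <- tibble::tibble(x = c(1, NA, 3, 4, 100), class = letters[c(1, 1, 2, 2, 1)])
#' p <- preprocess(d, outlier_factor = 1.5)
#' preprocess_report(p)
#' @export
preprocess <- function(data, sentinels = NULL, outlier_factor = 3,
                       extreme_factor = 6, class = "class",
                       quantile_type = 7) {
  data |>
    impute_missing(sentinels = sentinels, class = class) |>
    iqr_filter(outlier_factor = outlier_factor,
               extreme_factor = extreme_factor,
               class = class, quantile_type = quantile_type) |>
    minmax_scale(class = class)
}

#' Retrieve the preprocessing report
#'
#' Each preprocessing step records what it did (imputation counts per column,
#' outlier/extreme row counts, rows in/out, scaling parameters) in the
#' `report` attribute of its output; steps accumulate into one list.
#'
#' @param data Output of a preprocessing step or of [preprocess()].
#' @return A named list.
#' @export
preprocess_report <- function(data) {
  attr(data, "report")
}

attr_columns <- function(data, class) {
  cols <- setdiff(names(data), class)
  num <- vapply(data[cols], is.numeric, TRUE)
  if (!all(num)) {
    abort(sprintf("Non-numeric attribute column(s): %s.",
                  paste(cols[!num], collapse = ", ")))
  }
  cols
}

add_report <- function(out, input, entries) {
  rep <- preprocess_report(input) %||% list()
  attr(out, "report") <- utils::modifyList(rep, entries)
  out
}
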
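#' Specification for the synthetic class-structured generator
#'
#' Describes a labelled tabular dataset with class-dependent attribute
#' moments. Each class/attribute cell is drawn from a sinh-arcsinh
#' transformed Gaussian: with \eqn{Z \sim N(0,1)},
#' \deqn{S = \sinh\!\big((\mathrm{asinh}(Z) + \epsilon)/\tau\big),}
#' where `skew` (\eqn{\epsilon}) tilts the distribution left/right and `tail`
#' (\eqn{\tau}) thins (\eqn{\tau > 1}) or fattens (\eqn{\tau < 1}) the tails.
#' `S` is standardised by its own population mean and standard deviation
#' (computed by numerical integration, deterministically) before `location`
#' and `scale` are applied, so mean and variance are controlled independently
#' of skewness and tail weight — two classes can share mean and variance
#' exactly while differing only in skew.
#'
#' Missing-value sentinels and gross outliers can be injected at given rates
#' to emulate coded clinical data.
#'
#' @param n Named integer vector: rows per class (names are the class
#'   labels).
#' @param location,scale,skew,tail Per-class × per-attribute parameter
#'   matrices (classes in rows). Vectors are recycled: a length-`n_class`
#'   vector gives every attribute of a class the same value. `scale` must be
#'   positive.
#' @param missing_rate Probability that an attribute cell is replaced by
#'   `missing_sentinel`.
#' @param missing_sentinel Value marking injected missing cells (default
#'   `NA`).
#' @param outlier_rate Probability that a row receives one gross outlier
#'   cell.
#' @param outlier_scale Outlier magnitude, in units of the attribute's scale
#'   away from its location.
#' @return A `generator_spec` list, consumed by [synth_tabular()].
#' @export
generator_spec <- function(n, location, scale = 1, skew = 0, tail = 1,
                           missing_rate = 0, missing_sentinel = NA_real_,
                           outlier_rate = 0, outlier_scale = 10) {
  if (is.null(names(n))) names(n) <- paste0("c", seq_along(n))
  n_class <- length(n)
  if (any(n < 1)) abort("Every class needs at least one row.")
  as_mat <- function(p, nm) {
    if (is.matrix(p)) {
      if (nrow(p) != n_class) abort(sprintf("'%s' must have one row per class.", nm))
      p
    } else {
      matrix(p, nrow = n_class, ncol = max(1L, length(p) %/% n_class),
             byrow = FALSE)
    }
  }
  location <- as_mat(location, "location")
  d <- ncol(location)
  expand <- function(p, nm) {
    m <- as_mat(p, nm)
    if (ncol(m) == 1L && d > 1L) m <- m[, rep(1L, d), drop = FALSE]
    if (ncol(m) != d) abort(sprintf("'%s' must match the attribute count %d.", nm, d))
    m
  }
  scale <- expand(scale, "scale")
  if (any(scale <= 0)) abort("All scale parameters must be positive.")
  if (missing_rate < 0 || missing_rate > 1 || outlier_rate < 0 || outlier_rate > 1) {
    abort("Rates must lie in [0, 1].")
  }
  structure(
    list(n = n, location = location, scale = expand(scale, "scale"),
         skew = expand(skew, "skew"), tail = expand(tail, "tail"),
         missing_rate = missing_rate, missing_sentinel = missing_sentinel,
         outlier_rate = outlier_rate, outlier_scale = outlier_scale,
         n_attr = d),
    class = "generator_spec"
  )
}

## population mean and sd of sinh((asinh(Z)+skew)/tail), by quadrature
sas_norm <- function(skew, tail) {
  f <- function(z, p) sinh((asinh(z) + skew) / tail)^p * dnorm(z)
  m1 <- integrate(f, -Inf, Inf, p = 1, rel.tol = 1e-10)$value
  m2 <- integrate(f, -Inf, Inf, p = 2, rel.tol = 1e-10)$value
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

#' Generate a synthetic labelled table
#'
#' Draws the dataset described by a [generator_spec()], injects missing
#' sentinels and outliers, and returns the rows in shuffled order. All
#' randomness flows from the single `seed`.
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed.
#' @param class Name for the class column.
#' @return A tibble with `n_attr` numeric columns `x1..xd` and a `class`
#'   column.
#' @export
synth_tabular <- function(spec, seed = 1L, class = "class") {
  stopifnot(inherits(spec, "generator_spec"))
  local_rng(seed, {
    blocks <- purrr::map(seq_along(spec$n), function(ci) {
      nc <- spec$n[[ci]]
      cols <- purrr::map(seq_len(spec$n_attr), function(j) {
        eps <- spec$skew[ci, j]; tau <- spec$tail[ci, j]
        z <- rnorm(nc)
        s <- sinh((asinh(z) + eps) / tau)
        if (eps != 0 || tau != 1) {
          nrm <- sas_norm(eps, tau)
          s <- (s - nrm[["mean"]]) / nrm[["sd"]]
        }
        spec$location[ci, j] + spec$scale[ci, j] * s
      })
      x <- do.call(cbind, cols)
      ## gross outliers: one corrupted attribute in a fraction of rows
      out_rows <- which(stats::runif(nc) < spec$outlier_rate)
      for (r in out_rows) {
        j <- sample.int(spec$n_attr, 1L)
        x[r, j] <- spec$location[ci, j] +
          sign(stats::runif(1) - 0.5) * spec$outlier_scale * spec$scale[ci, j]
      }
      ## missing sentinels, cellwise
      if (spec$missing_rate > 0) {
        miss <- matrix(stats::runif(nc * spec$n_attr) < spec$missing_rate,
                       nrow = nc)
        x[miss] <- spec$missing_sentinel
      }
      colnames(x) <- paste0("x", seq_len(spec$n_attr))
      dplyr::mutate(as_tibble(x), !!class := names(spec$n)[ci])
    })
    out <- dplyr::bind_rows(blocks)
    out[sample.int(nrow(out)), , drop = FALSE]
  })
}

#' The five-point worked example
#'
#' A single-attribute class holding the values 5, 10, 15, 8, 20 — mean 11.6,
#' population third central moment 58.752. Handy as a smoke-test fixture.
#'
#' @return A tibble with columns `x` and `class`.
#' @export
worked_example <- function() {
  tibble(x = c(5, 10, 15, 8, 20), class = "c2")
}

#' Two-pass reference moments
#'
#' Independent brute-force oracle: computes the population `n`-th central
#' moment of a point set the naive way (mean first, then the average of
#' `n`-th-power deviations). Used to validate the incremental powered-sum
#' route; deliberately shares no code with it.
#'
#' @param x Numeric vector or matrix (columns = attributes).
#' @param n Moment order.
#' @return Per-attribute central moment (scalar for a vector input).
#' @export
oracle_moments <- function(x, n) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  out <- colMeans(sweep(x, 2, mu)^n)
  if (ncol(x) == 1L) unname(out) else out
}

#' Brute-force displacement scores
#'
#' Reference implementation of the MDEM scoring rule that re-materialises
#' every class's point set, appends the candidate point, recomputes the
#' scoring moment two-pass, and measures the weighted Euclidean displacement.
#' Ground truth for oracle-equivalence tests.
#'
#' @param class_sets Named list of numeric matrices (one per class, columns =
#'   attributes).
#' @param x Candidate attribute vector.
#' @param order Moment order (1 compares means).
#' @param weight `"count"` or `"count_plus_1"`.
#' @return A tibble with `class`, `raw`, `weighted`, `chosen`.
#' @export
oracle_displacements <- function(class_sets, x, order = 1L, weight = "count") {
  score_one <- function(pts) {
    pts <- as.matrix(pts)
    before <- if (order == 1L) colMeans(pts) else oracle_moments(pts, order)
    aug <- rbind(pts, x)
    after <- if (order == 1L) colMeans(aug) else oracle_moments(aug, order)
    raw <- sqrt(sum((as.numeric(after) - as.numeric(before))^2))
    w <- if (weight == "count") nrow(pts) else nrow(pts) + 1
    c(raw = raw, weighted = raw * w)
  }
  sc <- t(vapply(class_sets, score_one, c(raw = 0, weighted = 0)))
  tibble(
    class = names(class_sets) %||% paste0("c", seq_len(nrow(sc))),
    raw = unname(sc[, "raw"]),
    weighted = unname(sc[, "weighted"]),
    chosen = seq_len(nrow(sc)) == which.min(sc[, "weighted"])
  )
}
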
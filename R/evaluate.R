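#' k-fold assignment
#'
#' Randomly partitions `n` rows into `k` folds of size `floor(n/k)` or
#' `ceiling(n/k)` via a seeded permutation. Every row lands in exactly one
#' fold; the same seed always yields the same assignment.
#'
#' @param n Number of rows.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, length `n`.
#' @export
kfold_assign <- function(n, k, seed = 1L) {
  if (k < 2 || k > n) abort(sprintf("k must be in [2, %d]; got %s.", n, k))
  perm <- local_rng(seed, sample.int(n))
  fold <- integer(n)
  ## remainder rows spread over the first n %% k folds
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold[perm] <- rep(seq_len(k), times = sizes)
  fold
}

#' Stratified k-fold assignment
#'
#' As [kfold_assign()], but rows of each class are shuffled within class and
#' dealt round-robin to the folds, so every fold's class proportions match
#' the overall proportions to within one row per class.
#'
#' @param labels Class label per row.
#' @param k Number of folds; every class must have at least `k` rows.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_kfold_assign <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  if (k < 2 || k > n) abort(sprintf("k must be in [2, %d]; got %s.", n, k))
  tab <- table(labels)
  if (any(tab < k)) {
    abort(sprintf("Class(es) with fewer rows than k = %d: %s.",
                  k, paste(names(tab)[tab < k], collapse = ", ")))
  }
  fold <- integer(n)
  local_rng(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Binary confusion counts
#'
#' Tallies TP/FP/FN/TN for a declared positive class.
#'
#' @param truth,estimate Label vectors of equal length.
#' @param positive The label counted as positive.
#' @return Named integer vector `c(tp, fp, fn, tn)`.
#' @export
confusion_counts <- function(truth, estimate, positive) {
  truth <- as.character(truth); estimate <- as.character(estimate)
  c(tp = sum(truth == positive & estimate == positive),
    fp = sum(truth != positive & estimate == positive),
    fn = sum(truth == positive & estimate != positive),
    tn = sum(truth != positive & estimate != positive))
}

#' Classification metrics from a confusion matrix
#'
#' Standard binary metrics: accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)`, their harmonic mean F1, and the Matthews correlation
#' coefficient
#' \deqn{MCC = \frac{TP\,TN - FP\,FN}{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' A metric whose denominator is zero is reported as 0 and named in the
#' `flags` column (with a warning), rather than propagating `NaN`.
#'
#' @param cm Named vector with elements `tp`, `fp`, `fn`, `tn` (as produced by
#'   [confusion_counts()]).
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `f1`, `mcc`,
#'   `flags` (comma-separated names of zero-denominator metrics, or `""`).
#' @export
confusion_metrics <- function(cm) {
  cm <- cm[c("tp", "fp", "fn", "tn")]
  if (any(is.na(cm)) || any(cm < 0)) abort("Confusion counts must be non-negative.")
  total <- sum(cm)
  if (total == 0) abort("Empty confusion matrix.")
  tp <- cm[["tp"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]; tn <- cm[["tn"]]
  flags <- character(0)
  safe <- function(num, den, nm) {
    if (den == 0) {
      flags <<- c(flags, nm)
      0
    } else {
      num / den
    }
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f1 <- safe(2 * precision * recall, precision + recall, "f1")
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- safe(tp * tn - fp * fn, mcc_den, "mcc")
  if (length(flags)) {
    warn(sprintf("Zero denominator; reported as 0: %s.", paste(flags, collapse = ", ")))
  }
  tibble(
    accuracy = (tp + tn) / total,
    precision = precision, recall = recall, f1 = f1, mcc = mcc,
    flags = paste(flags, collapse = ",")
  )
}

#' Classifier specifications for cross-validation
#'
#' A classifier spec is a label plus `fit(train, class)` / `predict(fit, test)`
#' closures, the adapter interface [cross_validate()] and [accuracy_grid()]
#' consume. `mdem_spec()` wraps this package's classifier; the baseline
#' constructors adapt established implementations (logistic regression via
#' `stats::glm`, random forests via \pkg{randomForest}, support vector
#' machines via \pkg{e1071}, k-nearest-neighbour via \pkg{class}) for the
#' comparison grid — they are not re-implementations.
#'
#' @param order,evolve,weight Passed to [mdem()].
#' @param label Display label for result tables.
#' @return A `classifier_spec` list with elements `label`, `fit`, `predict`.
#' @export
mdem_spec <- function(order = 1L, evolve = TRUE, weight = "count",
                      label = NULL) {
  label <- label %||% paste0("MDEM (order ", order, ")")
  new_classifier_spec(
    label,
    fit = function(train, class) {
      mdem(train, class = class, order = order, evolve = evolve, weight = weight)
    },
    predict = function(fit, test) predict(fit, test)
  )
}

new_classifier_spec <- function(label, fit, predict) {
  structure(list(label = label, fit = fit, predict = predict),
            class = "classifier_spec")
}

#' @rdname mdem_spec
#' @export
lr_spec <- function(label = "Logistic Regression") {
  new_classifier_spec(
    label,
    fit = function(train, class) {
      y <- factor(train[[class]])
      if (nlevels(y) != 2) abort("Logistic-regression baseline is binary only.")
      x <- train[setdiff(names(train), class)]
      list(fit = stats::glm(y ~ ., data = cbind(x, y = y), family = stats::binomial()),
           levels = levels(y))
    },
    predict = function(fit, test) {
      p <- stats::predict(fit$fit, newdata = test, type = "response")
      fit$levels[(p > 0.5) + 1L]
    }
  )
}

#' @rdname mdem_spec
#' @param ntree,cost,neighbours Baseline hyperparameters.
#' @export
rf_spec <- function(ntree = 100, label = "Random Forest") {
  new_classifier_spec(
    label,
    fit = function(train, class) {
      rlang::check_installed("randomForest")
      x <- train[setdiff(names(train), class)]
      randomForest::randomForest(x, factor(train[[class]]), ntree = ntree)
    },
    predict = function(fit, test) as.character(stats::predict(fit, test))
  )
}

#' @rdname mdem_spec
#' @export
svm_spec <- function(cost = 1, label = "SVM") {
  new_classifier_spec(
    label,
    fit = function(train, class) {
      rlang::check_installed("e1071")
      x <- train[setdiff(names(train), class)]
      e1071::svm(x, factor(train[[class]]), cost = cost)
    },
    predict = function(fit, test) as.character(stats::predict(fit, test))
  )
}

#' @rdname mdem_spec
#' @export
knn_spec <- function(neighbours = 3, label = NULL) {
  label <- label %||% paste0("KNN (n = ", neighbours, ")")
  new_classifier_spec(
    label,
    fit = function(train, class) {
      rlang::check_installed("class")
      list(x = as.matrix(train[setdiff(names(train), class)]),
           y = factor(train[[class]]))
    },
    predict = function(fit, test) {
      as.character(class::knn(fit$x, as.matrix(test[, colnames(fit$x)]),
                              fit$y, k = neighbours))
    }
  )
}

#' Cross-validate a classifier
#'
#' Splits the rows into `k` folds (plain or stratified), fits a fresh model on
#' each k−1-fold training set — class states never leak across folds — and
#' predicts the held-out fold. Accuracy is reported as the mean of per-fold
#' accuracies (one number per configuration, as in the usual comparison
#' tables); precision, recall, F1 and MCC are computed on the confusion
#' matrix pooled over folds, which is stabler than averaging ratios over
#' small folds, and are also reported per fold.
#'
#' @param data Data frame of numeric attributes plus the class column
#'   (preprocess first; see [preprocess()]).
#' @param spec A `classifier_spec` (see [mdem_spec()]).
#' @param class Class column name.
#' @param k Number of folds.
#' @param stratified Use [stratified_kfold_assign()] instead of
#'   [kfold_assign()].
#' @param seed Integer seed driving the fold shuffle.
#' @param positive Positive class for the binary metrics; defaults to the
#'   minority class.
#' @return An `mdem_cv` object: `folds` (assignment vector), per-fold metric
#'   tibble, pooled confusion counts, aggregate metrics, and the call
#'   settings. Use [tidy()] for per-fold rows, [glance()] for the one-row
#'   summary, [autoplot()] for a fold-accuracy plot.
#' @examples
#' spec <- generator_spec(n = c(a = 40, b = 40), location = c(0, 1), scale = 0.1)
#' d <- synth_tabular(spec, seed = 1)
#' cv <- cross_validate(d, mdem_spec(order = 1), k = 5, seed = 1)
#' glance(cv)
#' @export
cross_validate <- function(data, spec = mdem_spec(), class = "class", k = 5,
                           stratified = FALSE, seed = 1L, positive = NULL) {
  data <- as_tibble(data)
  labels <- as.character(data[[class]])
  positive <- positive %||% minority_class(labels)
  folds <- if (stratified) {
    stratified_kfold_assign(labels, k, seed)
  } else {
    kfold_assign(nrow(data), k, seed)
  }
  per_fold <- purrr::map_dfr(seq_len(k), function(f) {
    train <- data[folds != f, , drop = FALSE]
    test <- data[folds == f, , drop = FALSE]
    missing <- setdiff(unique(labels), unique(train[[class]]))
    if (length(missing)) {
      abort(sprintf("Training split for fold %d is missing class(es): %s.",
                    f, paste(missing, collapse = ", ")))
    }
    fit <- spec$fit(train, class)
    pred <- spec$predict(fit, test[setdiff(names(test), class)])
    cm <- confusion_counts(test[[class]], pred, positive)
    m <- suppressWarnings(confusion_metrics(cm))
    dplyr::bind_cols(tibble(fold = f, n_test = nrow(test),
                            tp = cm[["tp"]], fp = cm[["fp"]],
                            fn = cm[["fn"]], tn = cm[["tn"]]), m)
  })
  pooled <- c(tp = sum(per_fold$tp), fp = sum(per_fold$fp),
              fn = sum(per_fold$fn), tn = sum(per_fold$tn))
  aggregate <- suppressWarnings(confusion_metrics(pooled))
  aggregate$accuracy <- mean(per_fold$accuracy) # per-fold mean, by convention
  structure(
    list(
      label = spec$label, folds = folds, per_fold = per_fold,
      pooled = pooled, aggregate = aggregate,
      k = k, stratified = stratified, seed = seed, positive = positive
    ),
    class = "mdem_cv"
  )
}

minority_class <- function(labels) {
  tab <- sort(table(labels))
  names(tab)[1L]
}

#' @export
print.mdem_cv <- function(x, ...) {
  cat(sprintf("%s — %s%d-fold CV (seed %d, positive class '%s')\n",
              x$label, if (x$stratified) "stratified " else "", x$k,
              x$seed, x$positive))
  cat(sprintf("  mean accuracy: %.4f | pooled precision %.3f, recall %.3f, F1 %.3f, MCC %.3f\n",
              x$aggregate$accuracy, x$aggregate$precision,
              x$aggregate$recall, x$aggregate$f1, x$aggregate$mcc))
  invisible(x)
}

#' @method tidy mdem_cv
#' @export
tidy.mdem_cv <- function(x, ...) {
  dplyr::mutate(x$per_fold, algorithm = x$label, .before = 1)
}

#' @method glance mdem_cv
#' @export
glance.mdem_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble(algorithm = x$label, k = x$k, stratified = x$stratified,
           seed = x$seed, positive = x$positive),
    x$aggregate
  )
}

#' @method autoplot mdem_cv
#' @export
autoplot.mdem_cv <- function(object, ...) {
  ggplot2::ggplot(object$per_fold,
                  ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$aggregate$accuracy,
                        linetype = "dashed") +
    ggplot2::labs(title = object$label, x = "fold", y = "accuracy") +
    ggplot2::theme_minimal()
}

#' Algorithm-by-k accuracy grid
#'
#' Runs [cross_validate()] for every classifier spec and every fold count and
#' assembles the familiar comparison table: one row per algorithm, one column
#' per `k`, mean CV accuracy in per cent.
#'
#' @inheritParams cross_validate
#' @param specs List of `classifier_spec`s.
#' @param ks Fold counts, e.g. `c(2, 3, 5, 7)`.
#' @return A tibble with column `algorithm` and one accuracy column per fold
#'   count (plus `metric = "accuracy_pct"`).
#' @export
accuracy_grid <- function(data, specs = list(mdem_spec(1), mdem_spec(2),
                                             mdem_spec(3), mdem_spec(4)),
                          class = "class", ks = c(2, 3, 5, 7),
                          stratified = FALSE, seed = 1L, positive = NULL) {
  purrr::map_dfr(specs, function(sp) {
    accs <- purrr::map_dbl(ks, function(k) {
      cv <- cross_validate(data, sp, class = class, k = k,
                           stratified = stratified, seed = seed,
                           positive = positive)
      100 * cv$aggregate$accuracy
    })
    dplyr::bind_cols(tibble(algorithm = sp$label),
                     setNames(as.list(accs), paste0(ks, "-fold")))
  })
}
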
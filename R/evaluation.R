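#' Confusion counts for binary predictions
#'
#' The positive class is lncRNA (label 1): TP are true lncRNAs predicted
#' as lncRNA, FN true lncRNAs predicted as mRNA, FP true mRNAs predicted
#' as lncRNA, TN true mRNAs predicted correctly.
#'
#' @param truth,pred Equal-length integer vectors over {0, 1}.
#' @return Named integer vector `c(tp, fn, fp, tn)`.
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("'truth' and 'pred' must have the same length")
  }
  stopifnot(all(truth %in% 0:1), all(pred %in% 0:1))
  c(tp = sum(truth == 1L & pred == 1L),
    fn = sum(truth == 1L & pred == 0L),
    fp = sum(truth == 0L & pred == 1L),
    tn = sum(truth == 0L & pred == 0L))
}

#' Threshold classification metrics
#'
#' Sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)`, accuracy
#' `(TP+TN)/total`, F1 `2TP/(2TP+FP+FN)` (the harmonic mean of
#' sensitivity and precision) and the geometric mean
#' `GM = sqrt(sensitivity * specificity)`, which remains informative on
#' imbalanced test sets. A metric whose denominator is zero is reported
#' as `NaN` with a warning rather than silently set to 0, so that fold
#' averages are not quietly corrupted.
#'
#' @param cc Confusion counts from [confusion()] (or any named vector
#'   with `tp`, `fn`, `fp`, `tn`).
#' @return Named numeric vector `c(sensitivity, precision, accuracy, f1,
#'   gm)`.
#' @export
classification_metrics <- function(cc) {
  tp <- cc[["tp"]]; fn <- cc[["fn"]]; fp <- cc[["fp"]]; tn <- cc[["tn"]]
  total <- tp + fn + fp + tn
  if (total == 0) stop("empty confusion counts")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as NaN")
      return(NaN)
    }
    num / den
  }
  sens <- safe_div(tp, tp + fn, "sensitivity")
  prec <- safe_div(tp, tp + fp, "precision")
  spec <- safe_div(tn, tn + fp, "specificity")
  c(sensitivity = sens,
    precision = prec,
    accuracy = (tp + tn) / total,
    f1 = safe_div(2 * tp, 2 * tp + fp + fn, "F1"),
    gm = sqrt(sens * spec))
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the observed confidence
#' probabilities (descending), building the ROC curve, and integrates it
#' by the trapezoidal rule. Tied scores form a single threshold step, so
#' the result equals the normalized Mann-Whitney U statistic with
#' rank-averaged ties.
#'
#' @param cp Confidence probabilities.
#' @param truth True labels over {0, 1}; both classes must be present.
#' @return A list: `auc` (numeric) and `curve` (`data.frame` with `fpr`,
#'   `tpr`, `threshold`).
#' @export
roc_auc <- function(cp, truth) {
  stopifnot(length(cp) == length(truth), all(truth %in% 0:1))
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("ROC requires at least one positive and one negative sample")
  }
  ord <- order(cp, decreasing = TRUE)
  cp_s <- cp[ord]; y <- truth[ord]
  last_of_block <- c(cp_s[-1] != cp_s[-length(cp_s)], TRUE)
  tp <- cumsum(y)[last_of_block]
  fp <- cumsum(1 - y)[last_of_block]
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc,
       curve = data.frame(fpr = fpr, tpr = tpr,
                          threshold = c(Inf, cp_s[last_of_block])))
}

#' Stratified k-fold assignment
#'
#' @param labels Integer labels over {0, 1}.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`, one per sample, with each
#'   class spread as evenly as possible across folds.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  if (min(table(labels)) < k) {
    stop("each class needs at least k samples for k-fold CV")
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      members <- which(labels == cl)
      folds[members] <- sample(rep_len(seq_len(k), length(members)))
    }
  })
  folds
}

#' Stratified k-fold cross-validation of one or more methods
#'
#' For each fold, `fit_predict(train, test)` is called with the two
#' transcript tables and must return a named list of confidence
#' probability vectors (one per method, aligned with `test` rows). Each
#' method's thresholded metrics and AUC are computed per fold.
#'
#' @param tr Labeled transcript `data.frame`.
#' @param fit_predict `function(train, test)` returning a named list of
#'   cp vectors.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return A list: `per_fold` (`data.frame` with `method`, `fold`, the
#'   five metrics and `auc`), `summary` (fold means per method), `folds`
#'   (the assignment vector).
#' @export
cross_validate <- function(tr, fit_predict, k = 5L, seed = 1L) {
  folds <- stratified_folds(tr$label, k = k, seed = seed)
  rows <- list()
  for (f in seq_len(k)) {
    train <- tr[folds != f, , drop = FALSE]
    test <- tr[folds == f, , drop = FALSE]
    cps <- fit_predict(train, test)
    stopifnot(is.list(cps), !is.null(names(cps)))
    for (method in names(cps)) {
      cp <- cps[[method]]
      m <- classification_metrics(confusion(test$label, to_label(cp)))
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, fold = f, t(m),
        auc = roc_auc(cp, test$label)$auc)
    }
  }
  per_fold <- do.call(rbind, rows)
  summary <- stats::aggregate(
    per_fold[, c("sensitivity", "precision", "accuracy", "f1", "gm", "auc")],
    by = list(method = per_fold$method), FUN = mean)
  list(per_fold = per_fold, summary = summary, folds = folds)
}

#' Fisher's least-significant-difference test on per-fold accuracies
#'
#' Classical (unprotected) LSD: a one-way ANOVA across methods provides
#' the pooled error mean square; each pair of methods is then compared by
#' `t = |mean_i - mean_j| / sqrt(MSE * 2 / n)` with the ANOVA error
#' degrees of freedom, giving a two-sided p-value. With zero variance
#' everywhere and equal means the difference is exactly zero and p = 1 is
#' reported.
#'
#' @param acc A named list of equal-length numeric vectors (per-fold
#'   accuracy per method), or a matrix/data.frame with one column per
#'   method.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return A list: `p` (symmetric matrix of pairwise p-values),
#'   `significant` (logical matrix, `p <= alpha`), `mse`, `df`.
#' @export
lsd_test <- function(acc, alpha = 0.05) {
  if (is.matrix(acc) || is.data.frame(acc)) {
    acc <- as.list(as.data.frame(acc))
  }
  g <- length(acc)
  if (g < 2L) stop("need at least two methods")
  n <- unique(lengths(acc))
  if (length(n) != 1L || n < 2L) {
    stop("all methods need the same number of folds (>= 2)")
  }
  means <- vapply(acc, mean, numeric(1))
  mse <- sum(vapply(acc, function(a) sum((a - mean(a))^2), numeric(1))) /
    (g * n - g)
  df <- g * n - g
  p <- matrix(1, g, g, dimnames = list(names(acc), names(acc)))
  for (i in seq_len(g - 1L)) {
    for (j in (i + 1L):g) {
      d <- abs(means[i] - means[j])
      if (d == 0) {
        pij <- 1
      } else if (mse == 0) {
        pij <- 0 # separated means with no within-method variance
      } else {
        tstat <- d / sqrt(mse * 2 / n)
        pij <- 2 * stats::pt(-tstat, df)
      }
      p[i, j] <- p[j, i] <- pij
    }
  }
  list(p = p, significant = p <= alpha, mse = mse, df = df)
}
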
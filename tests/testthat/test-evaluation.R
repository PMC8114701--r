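test_that("confusion counts follow the lncRNA-positive convention", {
  expect_equal(confusion(c(1, 1, 0, 0), c(1, 0, 1, 0)),
               c(tp = 1L, fn = 1L, fp = 1L, tn = 1L))
  truth <- rep(c(1L, 0L), 10L)
  expect_equal(confusion(truth, truth)[c("fn", "fp")], c(fn = 0L, fp = 0L))
  expect_equal(confusion(truth, 1L - truth)[c("tp", "tn")],
               c(tp = 0L, tn = 0L))
  expect_error(confusion(c(1, 0), c(1)), "length")
})

test_that("metrics reproduce the closed-form toy example", {
  m <- classification_metrics(c(tp = 9, fn = 1, fp = 2, tn = 8))
  expect_equal(m[["sensitivity"]], 0.9)
  expect_equal(m[["precision"]], 9 / 11)
  expect_equal(m[["accuracy"]], 0.85)
  expect_equal(m[["f1"]], 18 / 21)
  expect_equal(m[["gm"]], sqrt(0.9 * 0.8))
  perfect <- classification_metrics(c(tp = 5, fn = 0, fp = 0, tn = 5))
  expect_true(all(perfect == 1))
  zero <- suppressWarnings(
    classification_metrics(c(tp = 0, fn = 3, fp = 0, tn = 3)))
  expect_equal(zero[["sensitivity"]], 0)
  expect_equal(zero[["gm"]], 0)
  expect_warning(classification_metrics(c(tp = 0, fn = 0, fp = 1, tn = 1)),
                 "NaN")
})

test_that("metrics agree with loop-based counting on random labelings", {
  set.seed(41)
  for (rep in 1:200) {
    n <- sample(10:60, 1L)
    truth <- sample(0:1, n, replace = TRUE)
    pred <- sample(0:1, n, replace = TRUE)
    tp <- fn <- fp <- tn <- 0L
    for (i in seq_len(n)) {
      if (truth[i] == 1L && pred[i] == 1L) tp <- tp + 1L
      if (truth[i] == 1L && pred[i] == 0L) fn <- fn + 1L
      if (truth[i] == 0L && pred[i] == 1L) fp <- fp + 1L
      if (truth[i] == 0L && pred[i] == 0L) tn <- tn + 1L
    }
    cc <- confusion(truth, pred)
    expect_identical(cc, c(tp = tp, fn = fn, fp = fp, tn = tn))
    if (tp + fn > 0 && tp + fp > 0 && tn + fp > 0 && tp > 0) {
      m <- classification_metrics(cc)
      expect_equal(m[["f1"]],
                   2 * m[["precision"]] * m[["sensitivity"]] /
                     (m[["precision"]] + m[["sensitivity"]]))
      expect_equal(m[["gm"]], sqrt(m[["sensitivity"]] * tn / (tn + fp)))
    }
  }
})

test_that("AUC equals the rank-statistic (Mann-Whitney) oracle", {
  set.seed(43)
  for (rep in 1:200) {
    n <- sample(10:80, 1L)
    truth <- c(1L, 0L, sample(0:1, n - 2L, replace = TRUE))
    cp <- round(stats::runif(n), 1L) # coarse grid forces ties
    r <- rank(cp)
    n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
    u <- sum(r[truth == 1L]) - n1 * (n1 + 1) / 2
    expect_lt(abs(roc_auc(cp, truth)$auc - u / (n1 * n0)), 1e-12)
  }
})

test_that("ROC endpoints behave for perfect, constant and random scores", {
  truth <- rep(c(1L, 0L), each = 50L)
  expect_equal(roc_auc(c(stats::runif(50, 0.6, 1), stats::runif(50, 0, 0.4)),
                       truth)$auc, 1)
  expect_equal(roc_auc(rep(0.5, 100L), truth)$auc, 0.5)
  set.seed(47)
  rand <- roc_auc(stats::runif(2000), sample(0:1, 2000L, replace = TRUE))
  expect_gt(rand$auc, 0.45)
  expect_lt(rand$auc, 0.55)
  expect_error(roc_auc(stats::runif(5), rep(1L, 5L)), "positive and")
  curve <- roc_auc(stats::runif(30), rep(c(0L, 1L), 15L))$curve
  expect_equal(curve$fpr[1L], 0)
  expect_equal(utils::tail(curve$tpr, 1L), 1)
})

test_that("stratified folds balance both classes deterministically", {
  labels <- rep(c(1L, 0L), each = 100L)
  f <- stratified_folds(labels, k = 5L, seed = 3L)
  for (k in 1:5) {
    expect_equal(sum(f == k & labels == 1L), 20L)
    expect_equal(sum(f == k & labels == 0L), 20L)
  }
  expect_identical(f, stratified_folds(labels, k = 5L, seed = 3L))
  expect_error(stratified_folds(rep(c(0L, 1L), c(3L, 50L)), k = 5L),
               "at least k")
  expect_error(stratified_folds(labels, k = 1L), "at least 2")
})

test_that("cross-validation reports per-fold and averaged metrics", {
  tr <- toy_transcripts(25L, seed = 15L)
  # cheap stand-in classifiers: GC-content score and a coin flip
  fit_predict <- function(train, test) {
    gc <- function(s) {
      v <- strsplit(s, "")[[1]]
      mean(v %in% c("G", "C"))
    }
    mu <- mean(vapply(train$seq[train$label == 1L], gc, numeric(1)))
    score <- vapply(test$seq, gc, numeric(1))
    list(gc_rule = pmin(pmax(1 - abs(score - mu) * 5, 0), 1),
         constant = rep(0.5, nrow(test)))
  }
  cv <- cross_validate(tr, fit_predict, k = 5L, seed = 8L)
  expect_equal(nrow(cv$per_fold), 10L)
  expect_equal(sort(unique(cv$per_fold$method)), c("constant", "gc_rule"))
  expect_equal(nrow(cv$summary), 2L)
  expect_true(all(table(cv$folds) == 10L))
  acc <- cv$summary$accuracy[cv$summary$method == "gc_rule"]
  expect_gt(acc, 0.8) # strong-effect GC shift is easily separable
})

test_that("LSD test matches the closed-form pooled-variance oracle", {
  a <- c(0.95, 0.96, 0.95, 0.96, 0.95)
  b <- c(0.70, 0.71, 0.70, 0.69, 0.70)
  res <- lsd_test(list(m1 = a, m2 = b))
  n <- 5L
  mse <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (2L * n - 2L)
  tstat <- abs(mean(a) - mean(b)) / sqrt(mse * 2 / n)
  expect_equal(res$p["m1", "m2"], 2 * stats::pt(-tstat, 2L * n - 2L))
  expect_lte(res$p["m1", "m2"], 0.001)
  expect_true(res$significant["m1", "m2"])

  same <- lsd_test(list(x = a, y = a))
  expect_equal(same$p["x", "y"], 1)

  three <- lsd_test(list(a = a, b = b, c = b + 0.01))
  expect_equal(dim(three$p), c(3L, 3L))
  expect_equal(three$p, t(three$p))
  expect_error(lsd_test(list(a = a)), "two methods")
  expect_error(lsd_test(list(a = a, b = b[1:3])), "same number")
})
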
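test_that("stratified folds balance classes to within one patient", {
  # exact divisibility: 10 patients, 5 positive -> 1 + 1 per fold
  labels <- rep(c(1, 0), 5)
  folds <- stratified_kfold(labels, k = 5, seed = 1)
  for (f in 1:5) {
    expect_equal(sum(labels[folds == f]), 1)
    expect_equal(sum(folds == f), 2)
  }

  # 79 positives / 138 negatives: per-fold positive count in {15, 16}
  labels2 <- c(rep(1, 79), rep(0, 138))
  folds2 <- stratified_kfold(labels2, k = 5, seed = 3)
  pos_counts <- sapply(1:5, function(f) sum(labels2[folds2 == f]))
  expect_true(all(pos_counts %in% c(15, 16)))
  expect_equal(sum(pos_counts), 79)

  # determinism and partition property
  expect_identical(folds2, stratified_kfold(labels2, k = 5, seed = 3))
  expect_equal(sort(unique(folds2)), 1:5)
  expect_length(folds2, 217)

  expect_error(stratified_kfold(c(1, 0, 0, 0, 0, 0), k = 5), "fewer")
})

test_that("fold invariants hold over many random cohorts", {
  set.seed(20)
  for (i in 1:30) {
    n <- sample(20:150, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.6))
    if (min(sum(labels), n - sum(labels)) < 5) next
    folds <- stratified_kfold(labels, k = 5, seed = i)
    expect_length(folds, n)
    for (cl in 0:1) {
      counts <- sapply(1:5, function(f) sum(labels[folds == f] == cl))
      expect_lte(max(counts) - min(counts), 1)
    }
  }
})

test_that("compute_metrics matches enumerated pairwise concordance", {
  perfect <- compute_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(perfect$acc, 1)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$f1, 1)

  # ties count one half
  tied <- compute_metrics(c(1, 0, 1, 0), c(0.6, 0.6, 0.4, 0.4))
  expect_equal(tied$auc, 0.5)

  # enumerate the four positive-negative pairs by hand: 3 concordant
  m <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(m$acc, 0.5)
  expect_equal(m$auc, 3 / 4)

  expect_warning(m1 <- compute_metrics(c(1, 1), c(0.2, 0.9)), "one class")
  expect_true(is.na(m1$auc))
})

test_that("AUC equals the O(n^2) pairwise oracle with half-weight ties", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (min(sum(y), n - sum(y)) == 0) next
    p <- round(runif(n), sample(c(1, 2, 8), 1))  # coarse rounding forces ties
    pos <- p[y == 1]
    neg <- p[y == 0]
    cmp <- outer(pos, neg, "-")
    oracle <- (sum(cmp > 0) + 0.5 * sum(cmp == 0)) /
      (length(pos) * length(neg))
    expect_identical(compute_metrics(y, p)$auc, oracle)
  }
})

test_that("roc_points and average_roc produce valid averaged curves", {
  set.seed(22)
  y <- rbinom(60, 1, 0.4)
  p <- plogis(rnorm(60) + y)
  rc <- roc_points(y, p)
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  # area under the step curve equals the rank AUC
  area <- sum(diff(rc$fpr) * (rc$tpr[-1] + rc$tpr[-nrow(rc)]) / 2)
  expect_equal(area, compute_metrics(y, p)$auc, tolerance = 1e-10)

  avg <- average_roc(list(rc, rc))
  expect_equal(nrow(avg), 101)
  idx <- sapply(avg$fpr, function(fp) max(which(rc$fpr <= fp)))
  expect_equal(avg$tpr, rc$tpr[idx], tolerance = 1e-10)
})

test_that("crossval_run keeps folds patient-disjoint and reports per-fold metrics", {
  set.seed(23)
  n <- 40
  labels <- rbinom(n, 1, 0.4)
  # simple logistic samples: one informative scalar feature
  samples <- lapply(seq_len(n), function(i)
    list(patient_id = sprintf("Q%03d", i), x = labels[i] + rnorm(1, 0, 0.6)))
  trainer <- function(tr_s, tr_l) {
    x <- sapply(tr_s, function(s) s$x)
    fitcoef <- coef(glm(tr_l ~ x, family = binomial()))
    function(te_s) plogis(fitcoef[1] + fitcoef[2] *
                            sapply(te_s, function(s) s$x))
  }
  rep <- crossval_run(samples, labels, trainer, k = 5, seed = 2)
  expect_s3_class(rep, "metrics_report")
  expect_equal(nrow(rep$per_fold), 5)
  expect_equal(sum(rep$per_fold$n), n)
  expect_gt(rep$auc_mean, 0.7)
  expect_gte(rep$auc_sd, 0)
  # determinism of the whole harness
  rep2 <- crossval_run(samples, labels, trainer, k = 5, seed = 2)
  expect_identical(rep$per_fold, rep2$per_fold)
  # duplicate patient ids are refused (leakage guard)
  samples_dup <- samples
  samples_dup[[2]]$patient_id <- samples_dup[[1]]$patient_id
  expect_error(crossval_run(samples_dup, labels, trainer, k = 5, seed = 2),
               "duplicated")
})

test_that("cross-checked against an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(24)
  y <- rbinom(80, 1, 0.35)
  p <- runif(80)
  ours <- compute_metrics(y, p)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})
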
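#' Patient-level stratified k-fold assignment
#'
#' Randomly partitions patients into k folds following the class ratio:
#' within each class the (shuffled) patients are dealt round-robin over a
#' randomly rotated fold order, so per-fold class counts differ by at most
#' one patient from exact proportionality. Assignment is at patient level,
#' so all lesions of a patient share a fold.
#'
#' @param labels 0/1 vector, one entry per patient.
#' @param k number of folds (default 5).
#' @param seed integer seed; identical seeds give identical assignments.
#' @param patient_ids optional names for the returned vector.
#' @return Integer vector of fold indices in `1..k`, named by
#'   `patient_ids` when given.
#' @export
stratified_kfold <- function(labels, k = 5, seed = 1, patient_ids = NULL) {
  stopifnot(all(labels %in% c(0, 1)))
  n <- length(labels)
  for (cl in unique(labels)) {
    if (sum(labels == cl) < k) {
      stop("class ", cl, " has fewer than k = ", k, " patients")
    }
  }
  folds <- integer(n)
  with_local_seed(seed, {
    for (cl in c(1, 0)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold_order <- sample.int(k)
      folds[idx] <- rep(fold_order, length.out = length(idx))
    }
  })
  if (!is.null(patient_ids)) names(folds) <- patient_ids
  folds
}

#' Classification metrics: accuracy, AUC and F1
#'
#' AUC is the probability that a random positive outranks a random
#' negative, ties counted one half (computed via mean ranks, which equals
#' the pairwise-concordance definition exactly). Accuracy and F1 use the
#' fixed threshold; F1 is the harmonic mean of precision and recall for
#' the positive class (0 when there are no positive predictions or no
#' true positives).
#'
#' @param y_true 0/1 labels.
#' @param y_prob predicted probabilities.
#' @param threshold decision threshold for ACC/F1 (default 0.5).
#' @return List with `acc`, `auc`, `f1`, `threshold`. With a single-class
#'   input the AUC is undefined and returned as `NA` (with a warning),
#'   not silently 0.5.
#' @export
compute_metrics <- function(y_true, y_prob, threshold = 0.5) {
  stopifnot(length(y_true) == length(y_prob), length(y_true) > 0,
            all(y_true %in% c(0, 1)))
  pred <- as.integer(y_prob >= threshold)
  acc <- mean(pred == y_true)
  tp <- sum(pred == 1 & y_true == 1)
  fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  auc <- if (n_pos == 0 || n_neg == 0) {
    warning("AUC undefined: only one class present")
    NA_real_
  } else {
    r <- rank(y_prob)  # mean ranks handle ties as 1/2 concordance
    (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  list(acc = acc, auc = auc, f1 = f1, threshold = threshold)
}

#' Empirical ROC curve points
#'
#' Step-curve operating points swept over all distinct score thresholds,
#' from (0, 0) to (1, 1).
#'
#' @param y_true 0/1 labels (both classes present).
#' @param y_prob predicted probabilities.
#' @return Data frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(y_true, y_prob) {
  stopifnot(sum(y_true == 1) > 0, sum(y_true == 0) > 0)
  ord <- order(y_prob, decreasing = TRUE)
  y <- y_true[ord]
  p <- y_prob[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  keep <- c(p[-1] != p[-length(p)], TRUE)  # last point per tie group
  data.frame(fpr = c(0, fp[keep] / sum(y == 0)),
             tpr = c(0, tp[keep] / sum(y == 1)))
}

#' Vertically average ROC curves on a common FPR grid
#'
#' Each fold's step curve is interpolated at a fixed grid of
#' false-positive rates and the true-positive rates averaged, producing
#' the overall curve across folds.
#'
#' @param rocs list of data frames from [roc_points()].
#' @param grid FPR grid (default 101 points on `[0, 1]`).
#' @return Data frame with columns `fpr`, `tpr`.
#' @export
average_roc <- function(rocs, grid = seq(0, 1, by = 0.01)) {
  tprs <- vapply(rocs, function(rc) {
    stats::approx(rc$fpr, rc$tpr, xout = grid, method = "constant",
                  ties = max, rule = 2)$y
  }, numeric(length(grid)))
  data.frame(fpr = grid, tpr = rowMeans(as.matrix(tprs)))
}

#' Stratified cross-validated evaluation of a model-fitting routine
#'
#' Runs patient-level stratified k-fold cross-validation: for each fold a
#' model is fitted on the remaining folds by `trainer` and scored on the
#' held-out patients. A hard assertion guarantees no test patient appears
#' in its fold's training set.
#'
#' @param samples list of per-patient samples (passed through to
#'   `trainer` and the predictor it returns).
#' @param labels 0/1 vector, one per patient.
#' @param trainer `function(train_samples, train_labels)` returning a
#'   prediction function `function(test_samples) -> probabilities`.
#' @param k folds (default 5).
#' @param seed seed for the fold assignment.
#' @param threshold decision threshold for ACC/F1.
#' @param patient_ids optional patient identifiers (defaults to the
#'   samples' `patient_id` fields when present).
#' @return Object of class `metrics_report`: `per_fold` data frame,
#'   `auc_mean`, `auc_sd`, `acc`, `f1` (pooled over held-out
#'   predictions), `mean_roc`, `folds`, `threshold`, and the pooled
#'   held-out `y_true` / `y_prob`.
#' @export
crossval_run <- function(samples, labels, trainer, k = 5, seed = 1,
                         threshold = 0.5, patient_ids = NULL) {
  n <- length(samples)
  stopifnot(length(labels) == n)
  if (is.null(patient_ids)) {
    patient_ids <- vapply(seq_len(n), function(i) {
      pid <- samples[[i]]$patient_id
      if (is.null(pid)) sprintf("S%04d", i) else pid
    }, character(1))
  }
  if (anyDuplicated(patient_ids)) stop("duplicated patient ids")
  folds <- stratified_kfold(labels, k = k, seed = seed,
                            patient_ids = patient_ids)
  per_fold <- vector("list", k)
  rocs <- vector("list", k)
  oof_prob <- numeric(n)
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    if (length(intersect(patient_ids[test_idx],
                         patient_ids[train_idx])) > 0) {
      stop("fold leakage detected: a patient appears in both sets")
    }
    predict_fun <- trainer(samples[train_idx], labels[train_idx])
    probs <- predict_fun(samples[test_idx])
    oof_prob[test_idx] <- probs
    met <- compute_metrics(labels[test_idx], probs, threshold)
    per_fold[[f]] <- data.frame(fold = f, n = length(test_idx),
                                acc = met$acc, auc = met$auc, f1 = met$f1)
    rocs[[f]] <- roc_points(labels[test_idx], probs)
  }
  per_fold <- do.call(rbind, per_fold)
  pooled <- compute_metrics(labels, oof_prob, threshold)
  structure(list(per_fold = per_fold,
                 auc_mean = mean(per_fold$auc),
                 auc_sd = stats::sd(per_fold$auc),
                 acc = pooled$acc, f1 = pooled$f1,
                 mean_roc = average_roc(rocs), folds = folds,
                 threshold = threshold, y_true = labels,
                 y_prob = oof_prob),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report:", nrow(x$per_fold), "folds\n")
  cat(sprintf("  AUC  %.4f +/- %.4f (per-fold mean +/- sd)\n",
              x$auc_mean, x$auc_sd))
  cat(sprintf("  ACC  %.4f   F1 %.4f  (pooled, threshold %.2f)\n",
              x$acc, x$f1, x$threshold))
  invisible(x)
}
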
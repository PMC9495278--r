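#' Handcrafted radiomics features of one 2-D lesion
#'
#' Computes a fixed, documented 78-feature vector from a cropped image and
#' its lesion mask:
#'
#' * **Shape (4)** — `shape_area` (pixel count), `shape_perimeter`
#'   (number of exposed 4-neighbor edges), `shape_elongation`
#'   (`sqrt(lambda_minor / lambda_major)` of the pixel-coordinate
#'   covariance; 1 for a disc, smaller for elongated regions),
#'   `shape_max_diameter` (maximum pairwise pixel-center distance).
#' * **First order (14)**, over in-mask intensities — `mean`, `sd`
#'   (population), `skewness` (`m3 / m2^1.5`), `kurtosis` (`m4 / m2^2`,
#'   not excess), `entropy` (Shannon, bits, 32 equal-width bins over the
#'   in-mask range), `min`, `max`, percentiles 10/25/50/75/90, `iqr`,
#'   `energy` (sum of squares). Degenerate constant lesions give
#'   sd = skewness = kurtosis = entropy = 0.
#' * **GLCM (4)** — gray-level co-occurrence features on 32 levels
#'   (equal-width over the in-mask range), symmetric pairs restricted to
#'   the mask, averaged over the four standard unit offsets (0, 45, 90,
#'   135 degrees): `contrast`, `correlation` (1 when the marginal variance
#'   is zero), `energy` (angular second moment), `homogeneity`
#'   (inverse difference, `sum p / (1 + |i - j|)`).
#' * **Wavelet (4 x 14)** — the first-order set recomputed on the four
#'   sub-bands (LL, LH, HL, HH) of a one-level orthonormal Haar transform
#'   of the image, with the mask downsampled by 2x2 block maximum.
#'
#' @param image2d intensity matrix (unnormalized crop).
#' @param mask2d binary matrix of the same shape; must be nonempty.
#' @return Named numeric vector of length 78, fixed order, no missing
#'   values.
#' @export
radiomics_features <- function(image2d, mask2d) {
  if (!identical(dim(image2d), dim(mask2d))) stop("shape mismatch")
  if (sum(mask2d) == 0) stop("mask is empty")
  vals <- image2d[mask2d != 0]
  fo <- first_order_features(vals)
  out <- c(shape_features(mask2d),
           stats::setNames(fo, paste0("fo_", names(fo))),
           glcm_features(image2d, mask2d))
  wl <- haar_decompose(image2d)
  msk_ds <- block_max_downsample(mask2d)
  for (band in c("LL", "LH", "HL", "HH")) {
    fo <- first_order_features(wl[[band]][msk_ds != 0])
    out <- c(out, stats::setNames(fo, paste0("wavelet_", band, "_",
                                             names(fo))))
  }
  out
}

first_order_features <- function(vals) {
  n <- length(vals)
  mu <- mean(vals)
  m2 <- mean((vals - mu)^2)
  s <- sqrt(m2)
  skew <- if (m2 == 0) 0 else mean((vals - mu)^3) / m2^1.5
  kurt <- if (m2 == 0) 0 else mean((vals - mu)^4) / m2^2
  rng <- range(vals)
  ent <- if (rng[1] == rng[2]) 0 else {
    h <- tabulate(pmin(32L, findInterval(vals, seq(rng[1], rng[2],
                                                   length.out = 33L))), 32L)
    p <- h[h > 0] / n
    -sum(p * log2(p))
  }
  q <- stats::quantile(vals, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  c(mean = mu, sd = s, skewness = skew, kurtosis = kurt, entropy = ent,
    min = rng[1], max = rng[2], p10 = q[1], p25 = q[2], p50 = q[3],
    p75 = q[4], p90 = q[5], iqr = q[4] - q[2], energy = sum(vals^2))
}

shape_features <- function(mask2d) {
  idx <- which(mask2d != 0, arr.ind = TRUE)
  area <- nrow(idx)
  d <- dim(mask2d)
  padded <- matrix(0L, d[1] + 2L, d[2] + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1)] <- (mask2d != 0)
  perim <- sum(4L - (padded[cbind(idx[, 1], idx[, 2] + 1L)] +
                     padded[cbind(idx[, 1] + 2L, idx[, 2] + 1L)] +
                     padded[cbind(idx[, 1] + 1L, idx[, 2])] +
                     padded[cbind(idx[, 1] + 1L, idx[, 2] + 2L)]))
  elong <- if (area < 2) 1 else {
    cv <- stats::cov(idx) * (area - 1) / area  # population covariance
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    if (ev[1] <= 0) 1 else sqrt(max(ev[2], 0) / ev[1])
  }
  maxd <- if (area < 2) 0 else max(stats::dist(idx))
  c(shape_area = area, shape_perimeter = perim, shape_elongation = elong,
    shape_max_diameter = maxd)
}

quantize_levels <- function(vals, n_levels = 32L) {
  rng <- range(vals)
  if (rng[1] == rng[2]) return(rep(1L, length(vals)))
  pmin(n_levels,
       findInterval(vals, seq(rng[1], rng[2], length.out = n_levels + 1L)))
}

glcm_features <- function(image2d, mask2d, n_levels = 32L) {
  q <- matrix(NA_integer_, nrow(image2d), ncol(image2d))
  inm <- mask2d != 0
  q[inm] <- quantize_levels(image2d[inm], n_levels)
  offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  acc <- c(contrast = 0, correlation = 0, energy = 0, homogeneity = 0)
  n_used <- 0L
  idx <- which(inm, arr.ind = TRUE)
  d <- dim(image2d)
  for (off in offsets) {
    r2 <- idx[, 1] + off[1]
    c2 <- idx[, 2] + off[2]
    ok <- r2 >= 1 & r2 <= d[1] & c2 >= 1 & c2 <= d[2]
    ok[ok] <- inm[cbind(r2[ok], c2[ok])]
    if (!any(ok)) next
    i <- q[idx[ok, , drop = FALSE]]
    j <- q[cbind(r2[ok], c2[ok])]
    # symmetric GLCM: count both directions
    P <- matrix(0, n_levels, n_levels)
    for (t in seq_along(i)) {
      P[i[t], j[t]] <- P[i[t], j[t]] + 1
      P[j[t], i[t]] <- P[j[t], i[t]] + 1
    }
    P <- P / sum(P)
    lev <- seq_len(n_levels)
    pi_m <- rowSums(P)
    mu_i <- sum(lev * pi_m)
    var_i <- sum((lev - mu_i)^2 * pi_m)
    dif <- outer(lev, lev, "-")
    contrast <- sum(P * dif^2)
    corr <- if (var_i == 0) 1 else {
      sum(P * outer(lev - mu_i, lev - mu_i)) / var_i
    }
    acc <- acc + c(contrast = contrast, correlation = corr,
                   energy = sum(P^2),
                   homogeneity = sum(P / (1 + abs(dif))))
    n_used <- n_used + 1L
  }
  if (n_used == 0L) {
    return(c(glcm_contrast = 0, glcm_correlation = 1, glcm_energy = 1,
             glcm_homogeneity = 1))
  }
  stats::setNames(acc / n_used, paste0("glcm_", names(acc)))
}

#' One-level orthonormal 2-D Haar decomposition
#'
#' Splits an even-dimensioned matrix into LL/LH/HL/HH half-resolution
#' sub-bands. For the 2x2 block `[[A, C], [B, D]]` (row index first):
#' `LL = (A+B+C+D)/2`, `LH = (A-B+C-D)/2` (detail along rows),
#' `HL = (A+B-C-D)/2` (detail along columns), `HH = (A-B-C+D)/2`.
#'
#' @param image2d matrix with even numbers of rows and columns.
#' @return Named list of the four sub-band matrices.
#' @export
haar_decompose <- function(image2d) {
  d <- dim(image2d)
  if (any(d %% 2 != 0)) stop("Haar decomposition requires even dimensions")
  ri <- seq(1, d[1], by = 2)
  ci <- seq(1, d[2], by = 2)
  A <- image2d[ri, ci, drop = FALSE]
  B <- image2d[ri + 1, ci, drop = FALSE]
  C <- image2d[ri, ci + 1, drop = FALSE]
  D <- image2d[ri + 1, ci + 1, drop = FALSE]
  list(LL = (A + B + C + D) / 2, LH = (A - B + C - D) / 2,
       HL = (A + B - C - D) / 2, HH = (A - B - C + D) / 2)
}

block_max_downsample <- function(mask2d) {
  d <- dim(mask2d)
  ri <- seq(1, d[1], by = 2)
  ci <- seq(1, d[2], by = 2)
  pmax(mask2d[ri, ci, drop = FALSE], mask2d[ri + 1, ci, drop = FALSE],
       mask2d[ri, ci + 1, drop = FALSE],
       mask2d[ri + 1, ci + 1, drop = FALSE])
}

#' Radiomics feature matrix of a preprocessed cohort
#'
#' Extracts [radiomics_features()] from the raw (unnormalized) crop of
#' each requested view and binds them into one patient-by-feature matrix
#' with view-tagged column names (`sagittal__fo_mean`, ...).
#'
#' @param samples preprocessed samples from [preprocess_cohort()].
#' @param views view subset (default all three).
#' @return Numeric matrix, one row per patient.
#' @export
radiomics_feature_matrix <- function(samples,
                                     views = c("sagittal", "axial",
                                               "coronal")) {
  rows <- lapply(samples, function(s) {
    unlist(lapply(views, function(v) {
      fv <- radiomics_features(s$images_raw[[v]], s$masks[[v]])
      stats::setNames(fv, paste0(v, "__", names(fv)))
    }))
  })
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(samples, function(s) s$patient_id, character(1))
  X
}

#' Rank features by random-forest importance and keep the top set
#'
#' Fits a seeded random forest classifier and orders the features by mean
#' decrease in Gini impurity, returning the `n_keep` best in rank order.
#'
#' @param X feature matrix (patients x features, named columns).
#' @param y 0/1 labels.
#' @param n_keep number of features to keep (default 30).
#' @param seed seed for the forest.
#' @param ntree forest size (default 500).
#' @return Character vector of `n_keep` feature names, best first.
#' @export
rank_and_select <- function(X, y, n_keep = 30, seed = 1, ntree = 500) {
  stopifnot(ncol(X) >= n_keep, length(unique(y)) == 2)
  with_local_seed(seed, {
    rf <- randomForest::randomForest(x = X, y = factor(y), ntree = ntree)
    imp <- rf$importance[, "MeanDecreaseGini"]
    names(sort(imp, decreasing = TRUE))[seq_len(n_keep)]
  })
}

#' Gradient-boosting classification on the first half of the ranked set
#'
#' Trains a gradient boosting classifier on the first `n_use` (default 15,
#' the first half of the 30 retained) features of the ranked list and
#' predicts positive-class probabilities for the test rows.
#'
#' @param X_train,X_test feature matrices sharing column names.
#' @param y_train 0/1 training labels.
#' @param selected ranked feature names from [rank_and_select()].
#' @param n_use number of leading features to use (default 15).
#' @param seed seed for the booster.
#' @param nrounds boosting rounds (default 100).
#' @return Numeric vector of test-set probabilities.
#' @export
radiomics_classify <- function(X_train, y_train, X_test, selected,
                               n_use = 15, seed = 1, nrounds = 100) {
  use <- selected[seq_len(min(n_use, length(selected)))]
  missing_f <- setdiff(use, colnames(X_test))
  if (length(missing_f) > 0) {
    stop("features missing at test time: ",
         paste(missing_f, collapse = ", "))
  }
  with_local_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(X_train[, use, drop = FALSE],
                                   label = y_train)
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3,
                    eta = 0.1, nthread = 1),
      data = dtrain, nrounds = nrounds, verbose = 0)
    as.numeric(stats::predict(
      bst, xgboost::xgb.DMatrix(X_test[, use, drop = FALSE])))
  })
}

#' Cross-validated radiomics pipeline
#'
#' Runs the full baseline inside [crossval_run()]: per training fold,
#' random-forest ranking of the (single- or multi-view) feature matrix to
#' 30 features, gradient boosting on the first half, prediction on the
#' held-out fold. Feature selection is refit inside every training fold so
#' no selection leakage can occur; the per-fold ranked lists are returned
#' for inspection.
#'
#' @param samples preprocessed samples.
#' @param labels 0/1 vector.
#' @param views views whose features enter the matrix (all three gives
#'   the multi-view variant).
#' @param k,seed,threshold passed to [crossval_run()].
#' @param n_keep,n_use selection sizes (defaults 30 and 15).
#' @return A `metrics_report` with an extra `selected_features` element
#'   (list of per-fold ranked feature name vectors).
#' @export
radiomics_crossval <- function(samples, labels,
                               views = c("sagittal", "axial", "coronal"),
                               k = 5, seed = 1, threshold = 0.5,
                               n_keep = 30, n_use = 15) {
  X <- radiomics_feature_matrix(samples, views)
  selections <- list()
  trainer <- function(train_samples, train_labels) {
    ids <- vapply(train_samples, function(s) s$patient_id, character(1))
    Xtr <- X[ids, , drop = FALSE]
    sel <- rank_and_select(Xtr, train_labels, n_keep = n_keep, seed = seed)
    selections[[length(selections) + 1L]] <<- sel
    function(test_samples) {
      tids <- vapply(test_samples, function(s) s$patient_id, character(1))
      radiomics_classify(Xtr, train_labels, X[tids, , drop = FALSE], sel,
                         n_use = n_use, seed = seed)
    }
  }
  report <- crossval_run(samples, labels, trainer, k = k, seed = seed,
                         threshold = threshold)
  report$selected_features <- selections
  report
}
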
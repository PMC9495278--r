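test_that("degenerate constant lesions give textbook feature values", {
  img <- matrix(5, 8, 8)
  msk <- matrix(0L, 8, 8); msk[3:6, 3:6] <- 1L
  fv <- radiomics_features(img, msk)
  expect_equal(unname(fv["fo_sd"]), 0)
  expect_equal(unname(fv["fo_entropy"]), 0)
  expect_equal(unname(fv["glcm_energy"]), 1)
  expect_equal(unname(fv["glcm_contrast"]), 0)
  expect_equal(unname(fv["glcm_homogeneity"]), 1)
  expect_equal(unname(fv["shape_area"]), 16)
  expect_equal(unname(fv["shape_perimeter"]), 16)
  expect_length(fv, 78)
  expect_false(anyNA(fv))
})

test_that("the mean feature on a hand-set 3x3 lesion is the arithmetic mean", {
  img <- matrix(0, 6, 6)
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 18)
  img[2:4, 2:4] <- matrix(vals, 3, 3)
  msk <- matrix(0L, 6, 6); msk[2:4, 2:4] <- 1L
  fv <- radiomics_features(img, msk)
  expect_equal(unname(fv["fo_mean"]), mean(vals))
  expect_equal(unname(fv["fo_energy"]), sum(vals^2))
})

test_that("elongation orders circular before elongated masks of equal area", {
  disc <- matrix(0L, 20, 20)
  for (r in 1:20) for (cc in 1:20) {
    if ((r - 10)^2 + (cc - 10)^2 <= 16) disc[r, cc] <- 1L
  }
  bar <- matrix(0L, 20, 20)
  bar[9:10, 2:19] <- 1L
  img <- matrix(rnorm(400), 20, 20)
  e_disc <- radiomics_features(img, disc)["shape_elongation"]
  e_bar <- radiomics_features(img, bar)["shape_elongation"]
  expect_gt(unname(e_disc), unname(e_bar))
  expect_gt(unname(e_disc), 0.9)
  expect_lt(unname(e_bar), 0.3)
})

test_that("every native feature matches the brute-force oracle to 1e-8", {
  for (seed in 1:5) {
    lz <- random_lesion_2d(seed)
    fv <- radiomics_features(lz$img, lz$msk)
    vals <- lz$img[lz$msk != 0]
    fo <- naive_first_order(vals)
    for (nm in names(fo)) {
      expect_equal(unname(fv[paste0("fo_", nm)]), unname(fo[nm]),
                   tolerance = 1e-8, label = paste("fo", nm, "seed", seed))
    }
    gl <- naive_glcm(lz$img, lz$msk)
    expect_equal(unname(fv[c("glcm_contrast", "glcm_correlation",
                             "glcm_energy", "glcm_homogeneity")]),
                 unname(gl), tolerance = 1e-8)
    # shape oracles
    idx <- which(lz$msk != 0, arr.ind = TRUE)
    expect_equal(unname(fv["shape_area"]), nrow(idx))
    expect_equal(unname(fv["shape_max_diameter"]), max(dist(idx)),
                 tolerance = 1e-8)
    per <- 0
    for (t in seq_len(nrow(idx))) {
      for (off in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
        nb <- idx[t, ] + off
        outside <- any(nb < 1) || nb[1] > nrow(lz$msk) ||
          nb[2] > ncol(lz$msk) || lz$msk[nb[1], nb[2]] == 0
        if (outside) per <- per + 1
      }
    }
    expect_equal(unname(fv["shape_perimeter"]), per)
    # wavelet sub-bands: orthonormal Haar by explicit block arithmetic
    ds_msk <- matrix(0L, 8, 8)
    for (r in 1:8) for (cc in 1:8) {
      ds_msk[r, cc] <- max(lz$msk[(2 * r - 1):(2 * r),
                                  (2 * cc - 1):(2 * cc)])
    }
    LL <- matrix(0, 8, 8)
    for (r in 1:8) for (cc in 1:8) {
      blk <- lz$img[(2 * r - 1):(2 * r), (2 * cc - 1):(2 * cc)]
      LL[r, cc] <- sum(blk) / 2
    }
    fo_ll <- naive_first_order(LL[ds_msk != 0])
    expect_equal(unname(fv["wavelet_LL_mean"]), unname(fo_ll["mean"]),
                 tolerance = 1e-8)
    expect_equal(unname(fv["wavelet_LL_sd"]), unname(fo_ll["sd"]),
                 tolerance = 1e-8)
  }
})

test_that("haar_decompose reconstructs energy and halves resolution", {
  set.seed(50)
  img <- matrix(rnorm(16 * 16), 16, 16)
  wl <- haar_decompose(img)
  expect_identical(dim(wl$LL), c(8L, 8L))
  # orthonormal transform preserves total energy
  expect_equal(sum(img^2),
               sum(wl$LL^2) + sum(wl$LH^2) + sum(wl$HL^2) + sum(wl$HH^2),
               tolerance = 1e-10)
  expect_error(haar_decompose(matrix(0, 5, 6)), "even")
})

test_that("a planted discriminative feature is ranked first", {
  set.seed(60)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  hits <- 0
  for (seed in 1:5) {
    set.seed(seed * 7)
    X <- matrix(rnorm(n * 50), n,
                dimnames = list(NULL, paste0("f", 1:50)))
    X[, "f13"] <- y + rnorm(n, 0, 0.35)
    sel <- rank_and_select(X, y, n_keep = 30, seed = seed)
    if (sel[1] == "f13") hits <- hits + 1
    expect_length(sel, 30)
    expect_false(anyDuplicated(sel) > 0)
  }
  expect_gte(hits, 4)
  # duplicated columns still give 30 distinct names
  set.seed(61)
  X2 <- matrix(rnorm(n * 40), n,
               dimnames = list(NULL, paste0("g", 1:40)))
  X2 <- cbind(X2, X2[, 1:10, drop = FALSE])
  colnames(X2)[41:50] <- paste0("dup", 1:10)
  sel2 <- rank_and_select(X2, y, n_keep = 30, seed = 1)
  expect_length(unique(sel2), 30)
  # determinism
  expect_identical(rank_and_select(X2, y, seed = 9),
                   rank_and_select(X2, y, seed = 9))
})

test_that("gradient boosting on the first half separates planted signal", {
  set.seed(70)
  n <- 80
  y <- rep(c(0, 1), n / 2)
  X <- matrix(rnorm(n * 40), n, dimnames = list(NULL, paste0("f", 1:40)))
  X[, "f5"] <- y * 1.5 + rnorm(n, 0, 0.5)
  sel <- rank_and_select(X, y, n_keep = 30, seed = 2)
  tr <- 1:60
  p <- radiomics_classify(X[tr, ], y[tr], X[-tr, ], sel, seed = 2)
  expect_length(p, 20)
  expect_gt(compute_metrics(y[-tr], p)$auc, 0.8)
  # determinism under fixed seed
  p2 <- radiomics_classify(X[tr, ], y[tr], X[-tr, ], sel, seed = 2)
  expect_identical(p, p2)
  expect_error(radiomics_classify(X[tr, ], y[tr],
                                  X[-tr, 1:10], sel, seed = 2),
               "missing")
})

test_that("the multi-view radiomics matrix tags features by view and selection is per fold", {
  samples <- small_samples()
  labels <- sapply(samples, function(s) s$label)
  X <- radiomics_feature_matrix(samples)
  expect_equal(ncol(X), 78 * 3)
  expect_true(all(grepl("^(sagittal|axial|coronal)__", colnames(X))))
  expect_equal(nrow(X), length(samples))
  expect_false(anyNA(X))
  X1 <- radiomics_feature_matrix(samples, views = "sagittal")
  expect_equal(ncol(X1), 78)
})
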
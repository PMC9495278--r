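# Independent brute-force radiomics oracles shared by the unit and
# acceptance suites. These restate the documented formulas directly,
# without sharing code with the package internals.

naive_first_order <- function(vals) {
  n <- length(vals)
  mu <- sum(vals) / n
  m2 <- sum((vals - mu)^2) / n
  ent <- 0
  if (max(vals) > min(vals)) {
    edges <- seq(min(vals), max(vals), length.out = 33)
    counts <- numeric(32)
    for (v in vals) {
      b <- min(32, max(which(v >= edges[-33])))
      counts[b] <- counts[b] + 1
    }
    p <- counts[counts > 0] / n
    ent <- -sum(p * log2(p))
  }
  q <- stats::quantile(vals, c(.1, .25, .5, .75, .9), names = FALSE)
  c(mean = mu, sd = sqrt(m2),
    skewness = if (m2 == 0) 0 else (sum((vals - mu)^3) / n) / m2^1.5,
    kurtosis = if (m2 == 0) 0 else (sum((vals - mu)^4) / n) / m2^2,
    entropy = ent, min = min(vals), max = max(vals), p10 = q[1],
    p25 = q[2], p50 = q[3], p75 = q[4], p90 = q[5], iqr = q[4] - q[2],
    energy = sum(vals^2))
}

naive_glcm <- function(img, msk, n_levels = 32) {
  vals <- img[msk != 0]
  lev <- matrix(NA_integer_, nrow(img), ncol(img))
  if (max(vals) == min(vals)) {
    lev[msk != 0] <- 1L
  } else {
    edges <- seq(min(vals), max(vals), length.out = n_levels + 1)
    for (i in which(msk != 0)) {
      lev[i] <- min(n_levels, max(which(img[i] >= edges[-(n_levels + 1)])))
    }
  }
  feats <- matrix(NA_real_, 0, 4)
  for (off in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    P <- matrix(0, n_levels, n_levels)
    for (r in seq_len(nrow(img))) for (cc in seq_len(ncol(img))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 < 1 || r2 > nrow(img) || c2 < 1 || c2 > ncol(img)) next
      if (msk[r, cc] == 0 || msk[r2, c2] == 0) next
      P[lev[r, cc], lev[r2, c2]] <- P[lev[r, cc], lev[r2, c2]] + 1
      P[lev[r2, c2], lev[r, cc]] <- P[lev[r2, c2], lev[r, cc]] + 1
    }
    if (sum(P) == 0) next
    P <- P / sum(P)
    iL <- row(P); jL <- col(P)
    mu <- sum(iL * P)
    va <- sum((iL - mu)^2 * P)
    feats <- rbind(feats, c(
      sum(P * (iL - jL)^2),
      if (va == 0) 1 else sum(P * (iL - mu) * (jL - mu)) / va,
      sum(P^2),
      sum(P / (1 + abs(iL - jL)))))
  }
  colMeans(feats)
}

random_lesion_2d <- function(seed, size = 16) {
  set.seed(seed)
  img <- matrix(rnorm(size * size, 100, 15), size, size)
  msk <- matrix(0L, size, size)
  ctr <- sample(6:(size - 6), 2)
  rr <- sample(3:5, 1)
  for (r in seq_len(size)) for (cc in seq_len(size)) {
    if ((r - ctr[1])^2 + (cc - ctr[2])^2 <= rr^2) msk[r, cc] <- 1L
  }
  list(img = img, msk = msk)
}


random_lesion_2d <- function(seed, size = 16) {
  set.seed(seed)
  img <- matrix(rnorm(size * size, 100, 15), size, size)
  msk <- matrix(0L, size, size)
  ctr <- sample(6:(size - 6), 2)
  rr <- sample(3:5, 1)
  for (r in seq_len(size)) for (cc in seq_len(size)) {
    if ((r - ctr[1])^2 + (cc - ctr[2])^2 <= rr^2) msk[r, cc] <- 1L
  }
  list(img = img, msk = msk)
}
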
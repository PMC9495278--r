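# Shared fixtures, built once per test run and memoized.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- builder()
  fixture_env[[key]]
}

# A small phantom cohort with its preprocessed samples.
small_cohort <- function() {
  memo("small_cohort", function() generate_cohort(phantom_spec(
    n_patients = 8, seed = 42)))
}

small_samples <- function() {
  memo("small_samples", function() preprocess_cohort(small_cohort(),
                                                     crop_size = 32))
}

# A random ellipsoid-ish mask inside a grid, for geometry/shape oracles.
random_blob_mask <- function(shape, seed) {
  set.seed(seed)
  ctr <- shape / 2 + runif(3, -2, 2)
  semi <- runif(3, 2.5, min(shape) / 3)
  idx <- as.matrix(expand.grid(i = seq_len(shape[1]) - 1,
                               j = seq_len(shape[2]) - 1,
                               k = seq_len(shape[3]) - 1))
  d <- sqrt(((idx[, 1] - ctr[1]) / semi[1])^2 +
            ((idx[, 2] - ctr[2]) / semi[2])^2 +
            ((idx[, 3] - ctr[3]) / semi[3])^2)
  array(as.integer(d <= 1), shape)
}

# A tiny multi-view sample with random images and blob masks, for network
# and gradient tests (no phantom rendering needed).
tiny_sample <- function(seed, size = 16) {
  set.seed(seed)
  mk_mask <- function() {
    m <- matrix(0L, size, size)
    c0 <- sample(5:(size - 5), 2)
    m[(c0[1] - 2):(c0[1] + 2), (c0[2] - 2):(c0[2] + 2)] <- 1L
    m
  }
  views <- c("sagittal", "axial", "coronal")
  list(patient_id = sprintf("T%03d", seed),
       images = setNames(lapply(views, function(v)
         matrix(rnorm(size * size), size, size)), views),
       masks = setNames(lapply(views, function(v) mk_mask()), views),
       label = sample(0:1, 1))
}

tiny_model <- function(seed = 3, channels = c(4, 6)) {
  init_model(config = backbone_config(channels = channels), r = 10,
             seed = seed)
}
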
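#' Backbone configuration
#'
#' The default backbone is `small_cnn`: a stack of 3x3 convolutions with
#' ReLU, one per entry of `channels`; every block downsamples by stride 2
#' except the last, which keeps its resolution so the feature map (and the
#' class-activation attention derived from it) retains some spatial
#' detail. The final entry of `channels` is the feature channel count C.
#' It is compact enough to train on one CPU. The
#' `resnet50` name is reserved for a pretrained large backbone and is not
#' constructible here because pretrained weights are not shipped; requesting
#' it raises an informative error.
#'
#' @param name `"small_cnn"` or `"resnet50"`.
#' @param channels integer vector of output channels per conv block; the
#'   last entry is the feature channel count C.
#' @param in_channels input image channels (1 for a single MR sequence).
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(name = c("small_cnn", "resnet50"),
                            channels = c(4, 8, 16, 32), in_channels = 1L) {
  name <- match.arg(name)
  if (name == "resnet50") {
    stop("the resnet50 backbone requires pretrained weights, which are ",
         "not bundled; use the small_cnn backbone")
  }
  stopifnot(length(channels) >= 1, all(channels >= 1))
  n <- length(channels)
  strides <- if (n == 1) 2L else c(rep(2L, n - 1), 1L)
  structure(list(name = name, channels = as.integer(channels),
                 in_channels = as.integer(in_channels),
                 strides = strides,
                 feature_channels = as.integer(channels[length(channels)])),
            class = "backbone_config")
}

he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dims)
}

#' Initialize a multi-view attention-guided model
#'
#' Builds one backbone per view plus a single fully connected head with a
#' sigmoid output on the concatenation of the per-view LSE-pooled feature
#' vectors. All parameters use He-uniform initialization. Weights are
#' per-view (branches are not shared).
#'
#' @param views character subset of `c("sagittal", "axial", "coronal")`,
#'   in the fixed concatenation order.
#' @param config a [backbone_config()].
#' @param r log-sum-exp pooling sharpness (> 0); intermediate between mean
#'   (r -> 0) and max (r -> Inf) pooling.
#' @param seed integer seed for the initialization.
#' @return Object of class `mvattn_model`.
#' @export
init_model <- function(views = c("sagittal", "axial", "coronal"),
                       config = backbone_config(), r = 10, seed = 1) {
  stopifnot(length(views) >= 1, r > 0,
            all(views %in% c("sagittal", "axial", "coronal")))
  views <- intersect(c("sagittal", "axial", "coronal"), views)
  C <- config$feature_channels
  with_local_seed(seed, {
    backbones <- lapply(views, function(v) {
      ic <- config$in_channels
      layers <- lapply(config$channels, function(oc) {
        fan_in <- 3 * 3 * ic
        layer <- list(W = he_uniform(c(3, 3, ic, oc), fan_in),
                      b = numeric(oc))
        ic <<- oc
        layer
      })
      layers
    })
    names(backbones) <- views
    nF <- length(views) * C
    head <- list(w = as.numeric(he_uniform(nF, nF)), b = 0)
    structure(list(views = views, config = config, r = r,
                   backbones = backbones, head = head, C = C),
              class = "mvattn_model")
  })
}

#' @export
print.mvattn_model <- function(x, ...) {
  cat("mvattn_model:", length(x$views), "view(s) [",
      paste(x$views, collapse = ", "), "]\n")
  cat("  backbone:", x$config$name, "- channels",
      paste(x$config$channels, collapse = "/"),
      "; LSE r =", x$r, "\n")
  cat("  head: fully connected on", length(x$head$w),
      "pooled features + sigmoid\n")
  invisible(x)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Extract the convolutional feature map for one view
#'
#' Runs the view's backbone on a normalized 2-D image. Deterministic given
#' fixed weights.
#'
#' @param model a `mvattn_model`.
#' @param view view name.
#' @param image2d normalized H x W intensity matrix.
#' @return List with `fmap` (h x w x C post-ReLU feature map) and `cache`
#'   (per-layer pre/post activations, needed for the backward pass).
#' @export
extract_features <- function(model, view, image2d) {
  layers <- model$backbones[[view]]
  if (is.null(layers)) stop("model has no backbone for view: ", view)
  x <- array(as.double(image2d),
             c(nrow(image2d), ncol(image2d), model$config$in_channels))
  cache <- list()
  strides <- model$config$strides
  for (li in seq_along(layers)) {
    pre <- .conv2d_fwd(x, layers[[li]]$W, layers[[li]]$b, strides[li], 1L)
    post <- relu(pre)
    cache[[li]] <- list(input = x, pre = pre)
    x <- post
  }
  list(fmap = x, cache = cache)
}

#' Log-sum-exp spatial pooling
#'
#' Per channel, `(1/r) * log(mean(exp(r * x)))` over all spatial
#' positions, numerically stabilized by subtracting the per-channel
#' maximum before exponentiation. Interpolates between mean pooling
#' (r -> 0) and max pooling (r -> Inf).
#'
#' @param feature_map h x w x C array (or h x w matrix for C = 1).
#' @param r sharpness parameter, > 0.
#' @return Length-C numeric vector.
#' @export
lse_pool <- function(feature_map, r) {
  if (r <= 0) stop("LSE sharpness r must be > 0")
  if (is.matrix(feature_map)) {
    feature_map <- array(feature_map, c(dim(feature_map), 1L))
  }
  d <- dim(feature_map)
  m <- matrix(feature_map, d[1] * d[2], d[3])
  mx <- apply(m, 2L, max)
  sweep_e <- exp(sweep(m, 2L, mx, "-") * r)
  mx + log(colMeans(sweep_e)) / r
}

# softmax weights of LSE pooling (the pooling gradient), h*w x C matrix
lse_pool_weights <- function(feature_map, r) {
  d <- dim(feature_map)
  m <- matrix(feature_map, d[1] * d[2], d[3])
  mx <- apply(m, 2L, max)
  e <- exp(sweep(m, 2L, mx, "-") * r)
  sweep(e, 2L, colSums(e), "/")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Fuse pooled view features and classify
#'
#' Concatenates the pooled feature vectors in the model's fixed view order
#' and applies the fully connected head with a sigmoid, yielding the
#' positive-class probability.
#'
#' @param pooled named list (by view) of length-C pooled vectors, or a
#'   single concatenated numeric vector.
#' @param head list with weight vector `w` and scalar bias `b`.
#' @return Probability strictly inside (0, 1).
#' @export
fuse_and_classify <- function(pooled, head) {
  f <- if (is.list(pooled)) unlist(pooled, use.names = FALSE) else pooled
  if (length(f) != length(head$w)) {
    stop("pooled feature length ", length(f),
         " does not match head width ", length(head$w))
  }
  sigmoid(sum(head$w * f) + head$b)
}

#' Forward pass of the multi-view model
#'
#' Composition extract -> LSE pool -> concatenate -> FC + sigmoid. The
#' per-view feature maps are retained for the attention module.
#'
#' @param model a `mvattn_model`.
#' @param sample preprocessed sample with `images[[view]]` for every view
#'   of the model (missing views are an error: there is no silent
#'   single-view fallback).
#' @return List with `prob`, `fmaps` (named per-view post-ReLU feature
#'   maps), `pooled` (named pooled vectors) and `caches` (for backprop).
#' @export
forward <- function(model, sample) {
  for (v in model$views) {
    if (is.null(sample$images[[v]])) stop("sample is missing view: ", v)
  }
  fmaps <- list(); caches <- list(); pooled <- list()
  for (v in model$views) {
    ex <- extract_features(model, v, sample$images[[v]])
    fmaps[[v]] <- ex$fmap
    caches[[v]] <- ex$cache
    pooled[[v]] <- lse_pool(ex$fmap, model$r)
  }
  list(prob = fuse_and_classify(pooled, model$head), fmaps = fmaps,
       pooled = pooled, caches = caches)
}

# Head weight block belonging to one view (the 3C head is partitioned in
# the fixed view order).
head_weights_for_view <- function(model, view) {
  i <- match(view, model$views)
  if (is.na(i)) stop("unknown view: ", view)
  model$head$w[((i - 1) * model$C + 1):(i * model$C)]
}
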
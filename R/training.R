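#' Training configuration
#'
#' Defaults follow the standard protocol for this model: Adam with initial learning rate
#' 1e-3 reduced by 10% every 5 epochs (multiplicative 0.9 per 5-epoch
#' block), batch size 16, He-uniform initialization, attention-loss weight
#' 0.5. The epoch budget is configurable (not stated in the protocol;
#' default 50).
#'
#' @param epochs number of epochs.
#' @param batch_size samples per optimization step.
#' @param initial_lr initial learning rate.
#' @param lr_decay multiplicative decay factor per block.
#' @param lr_decay_every block length in epochs.
#' @param lambda attention supervision weight (0 disables it exactly).
#' @param attention logical; compute and supervise attention maps.
#' @param views view subset (fixed order sagittal, axial, coronal).
#' @param r LSE pooling sharpness.
#' @param channels backbone conv channels.
#' @param seed seed controlling initialization and batch shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 50, batch_size = 16, initial_lr = 1e-3,
                         lr_decay = 0.9, lr_decay_every = 5, lambda = 0.5,
                         attention = TRUE,
                         views = c("sagittal", "axial", "coronal"),
                         r = 10, channels = c(4, 8, 16, 32), seed = 1) {
  stopifnot(epochs >= 1, batch_size >= 1, initial_lr > 0, lambda >= 0,
            length(views) >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, lr_decay = lr_decay,
                 lr_decay_every = as.integer(lr_decay_every),
                 lambda = lambda, attention = attention,
                 views = intersect(c("sagittal", "axial", "coronal"), views),
                 r = r, channels = channels, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Step decay: `initial_lr * lr_decay ^ floor(epoch / lr_decay_every)`
#' with 0-based epochs, i.e. a 10% reduction applied once per 5-epoch
#' block under the defaults.
#'
#' @param config a [train_config()].
#' @param epoch 0-based epoch index.
#' @return Learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  stopifnot(epoch >= 0)
  config$initial_lr * config$lr_decay ^ (epoch %/% config$lr_decay_every)
}

zero_like_model <- function(model) {
  g <- list(backbones = lapply(model$backbones, function(layers) {
    lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  }), head = list(w = model$head$w * 0, b = 0))
  g
}

flatten_params <- function(tree, views) {
  parts <- list()
  for (v in views) {
    for (l in tree$backbones[[v]]) {
      parts[[length(parts) + 1L]] <- as.numeric(l$W)
      parts[[length(parts) + 1L]] <- as.numeric(l$b)
    }
  }
  parts[[length(parts) + 1L]] <- as.numeric(tree$head$w)
  parts[[length(parts) + 1L]] <- as.numeric(tree$head$b)
  unlist(parts, use.names = FALSE)
}

set_params <- function(model, vec) {
  pos <- 1L
  take <- function(n) {
    out <- vec[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  for (v in model$views) {
    for (li in seq_along(model$backbones[[v]])) {
      W <- model$backbones[[v]][[li]]$W
      model$backbones[[v]][[li]]$W <- array(take(length(W)), dim(W))
      b <- model$backbones[[v]][[li]]$b
      model$backbones[[v]][[li]]$b <- take(length(b))
    }
  }
  model$head$w <- take(length(model$head$w))
  model$head$b <- take(1L)
  stopifnot(pos == length(vec) + 1L)
  model
}

# Loss and full analytic gradient for one sample. The attention path
# backpropagates through min-max normalization, bilinear upsampling,
# rectification and the CAM channel weighting into both the feature maps
# and the head weights.
sample_loss_grad <- function(model, sample, label, lambda, attention,
                             want_grad = TRUE) {
  fw <- forward(model, sample)
  p <- fw$prob
  eps <- 1e-7
  pc <- min(max(p, eps), 1 - eps)
  Lc <- -(label * log(pc) + (1 - label) * log(1 - pc))
  Ls <- c(sagittal = 0, axial = 0, coronal = 0)
  g <- if (want_grad) zero_like_model(model) else NULL
  dz <- p - label
  Fcat <- unlist(fw$pooled, use.names = FALSE)
  if (want_grad) {
    g$head$w <- g$head$w + dz * Fcat
    g$head$b <- g$head$b + dz
  }
  C <- model$C
  for (vi in seq_along(model$views)) {
    v <- model$views[vi]
    A <- fw$fmaps[[v]]
    d <- dim(A)
    hw <- d[1] * d[2]
    Aflat <- matrix(A, hw, C)
    w_v <- head_weights_for_view(model, v)
    gA <- NULL
    if (want_grad) {
      gf <- dz * w_v
      sm <- lse_pool_weights(A, model$r)
      gA <- sweep(sm, 2L, gf, "*")
    }
    if (attention && lambda > 0) {
      mask <- sample$masks[[v]]
      if (is.null(mask)) stop("attention supervision requires a mask for ",
                              "view ", v)
      HW <- dim(mask)
      m <- matrix(Aflat %*% w_v, d[1], d[2])
      mr <- relu(m)
      up <- .bilinear_up(mr, HW[1], HW[2])
      lo <- min(up)
      hi <- max(up)
      npix <- HW[1] * HW[2]
      if (hi - lo <= 1e-12) {
        s <- up * 0
        Ls[v] <- mean((mask - s)^2)
        # constant rectified map: normalization is pinned at zero and the
        # subgradient through it is taken as zero
      } else {
        D <- hi - lo
        s <- (up - lo) / D
        Ls[v] <- mean((mask - s)^2)
        if (want_grad) {
          gs <- 2 * (s - mask) / npix * lambda
          gup <- gs / D
          jmin <- which.min(up)
          jmax <- which.max(up)
          gup[jmin] <- gup[jmin] - sum(gs) / D
          tshift <- sum(gs * (up - lo)) / D^2
          gup[jmax] <- gup[jmax] - tshift
          gup[jmin] <- gup[jmin] + tshift
          gmr <- .bilinear_up_bwd(gup, d[1], d[2])
          gm <- gmr * (m > 0)
          gA <- gA + as.numeric(gm) %o% w_v
          gw_att <- as.numeric(t(Aflat) %*% as.numeric(gm))
          idx <- ((vi - 1) * C + 1):(vi * C)
          g$head$w[idx] <- g$head$w[idx] + gw_att
        }
      }
    }
    if (want_grad) {
      gpost <- array(gA, d)
      cache <- fw$caches[[v]]
      for (li in rev(seq_along(cache))) {
        gpre <- gpost * (cache[[li]]$pre > 0)
        bwd <- .conv2d_bwd(cache[[li]]$input,
                           model$backbones[[v]][[li]]$W, gpre,
                           model$config$strides[li], 1L)
        g$backbones[[v]][[li]]$W <- g$backbones[[v]][[li]]$W + bwd$gw
        g$backbones[[v]][[li]]$b <- g$backbones[[v]][[li]]$b + bwd$gb
        gpost <- bwd$gx
      }
    }
  }
  L <- Lc + lambda * sum(Ls)
  list(L = L, Lc = Lc, Ls = Ls, prob = p, grad = g)
}

#' Total training loss of one sample (diagnostic)
#'
#' Classification loss plus `lambda` times the summed per-view attention
#' losses, computed exactly as inside the training loop. Useful for
#' finite-difference verification of the analytic gradients.
#'
#' @param model a `mvattn_model`.
#' @param sample preprocessed multi-view sample.
#' @param label 0/1 class label.
#' @param lambda attention weight.
#' @param attention logical; include the attention term.
#' @return Scalar loss.
#' @export
sample_total_loss <- function(model, sample, label, lambda = 0.5,
                              attention = TRUE) {
  sample_loss_grad(model, sample, label, lambda, attention,
                   want_grad = FALSE)$L
}

#' Analytic parameter gradient of the total loss for one sample
#'
#' @inheritParams sample_total_loss
#' @return List with the scalar `L` and `grad`, a flat numeric vector in
#'   the model's canonical parameter order (see [sample_total_loss()] for
#'   the corresponding loss).
#' @export
sample_gradient <- function(model, sample, label, lambda = 0.5,
                            attention = TRUE) {
  res <- sample_loss_grad(model, sample, label, lambda, attention)
  list(L = res$L, grad = flatten_params(res$grad, model$views))
}

#' Train a multi-view attention-guided classifier
#'
#' Mini-batch Adam on the combined objective: binary cross-entropy of the
#' fused prediction plus `lambda` times the summed per-view mean-squared
#' error between each CAM attention map and the lesion label map. With
#' `attention = FALSE` or `lambda = 0` the attention machinery is inert
#' and plain classification training results.
#'
#' @param samples list of preprocessed multi-view samples.
#' @param labels integer 0/1 vector, one per sample.
#' @param config a [train_config()].
#' @return List with the trained `model` and a `history` data frame
#'   (epoch, lr, Lc, Ls_all, L).
#' @export
train <- function(samples, labels, config = train_config()) {
  stopifnot(length(samples) == length(labels), length(samples) >= 1)
  n <- length(samples)
  if (config$attention && config$lambda > 0) {
    for (s in samples) {
      for (v in config$views) {
        if (is.null(s$masks[[v]])) {
          stop("attention training requires masks for every view; missing ",
               v, " for ", s$patient_id)
        }
      }
    }
  }
  model <- init_model(views = config$views,
                      config = backbone_config(channels = config$channels),
                      r = config$r, seed = config$seed)
  theta <- flatten_params(model, model$views)
  m_adam <- numeric(length(theta))
  v_adam <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps_adam <- 1e-8
  t_adam <- 0L
  history <- vector("list", config$epochs)
  with_local_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs) - 1L) {
      lr <- lr_at_epoch(config, epoch)
      ord <- sample.int(n)
      ep_Lc <- 0; ep_Ls <- 0; ep_L <- 0
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (batch in batches) {
        gacc <- numeric(length(theta))
        bLc <- 0; bLs <- 0
        for (i in batch) {
          res <- sample_loss_grad(model, samples[[i]], labels[i],
                                  config$lambda,
                                  config$attention && config$lambda > 0)
          gacc <- gacc + flatten_params(res$grad, model$views)
          bLc <- bLc + res$Lc
          bLs <- bLs + sum(res$Ls)
        }
        nb <- length(batch)
        gacc <- gacc / nb
        bL <- bLc / nb + config$lambda * bLs / nb
        if (!is.finite(bL)) {
          stop("non-finite loss at epoch ", epoch, "; aborting (check ",
               "learning rate and input scaling)")
        }
        t_adam <- t_adam + 1L
        m_adam <- b1 * m_adam + (1 - b1) * gacc
        v_adam <- b2 * v_adam + (1 - b2) * gacc^2
        mhat <- m_adam / (1 - b1^t_adam)
        vhat <- v_adam / (1 - b2^t_adam)
        theta <- theta - lr * mhat / (sqrt(vhat) + eps_adam)
        model <- set_params(model, theta)
        ep_Lc <- ep_Lc + bLc
        ep_Ls <- ep_Ls + bLs
        ep_L <- ep_L + bL * nb
      }
      history[[epoch + 1L]] <- data.frame(
        epoch = epoch, lr = lr, Lc = ep_Lc / n, Ls_all = ep_Ls / n,
        L = ep_L / n)
    }
  })
  list(model = model, history = do.call(rbind, history))
}

#' Train a single-view ablation model
#'
#' Same architecture and objective restricted to one view; the head acts
#' on a length-C pooled vector.
#'
#' @param samples,labels as in [train()].
#' @param view one of `"sagittal"`, `"axial"`, `"coronal"`.
#' @param config a [train_config()]; its `views` field is overridden.
#' @return As [train()].
#' @export
train_single_view <- function(samples, labels, view, config = train_config()) {
  stopifnot(view %in% c("sagittal", "axial", "coronal"))
  config$views <- view
  train(samples, labels, config)
}

#' Predicted positive-class probabilities for a set of samples
#'
#' @param model a trained `mvattn_model`.
#' @param samples list of preprocessed multi-view samples.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, samples) {
  vapply(samples, function(s) forward(model, s)$prob, numeric(1))
}
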
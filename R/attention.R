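#' Min-max normalize a nonnegative map to [0, 1]
#'
#' Maps with a (near-)constant value are returned as all zeros rather than
#' amplifying numerical noise (epsilon guard).
#'
#' @param m numeric matrix.
#' @param eps degeneracy guard on the value range.
#' @return Matrix in `[0, 1]`.
#' @keywords internal
minmax_normalize <- function(m, eps = 1e-12) {
  lo <- min(m)
  hi <- max(m)
  if (hi - lo <= eps) return(m * 0)
  (m - lo) / (hi - lo)
}

#' Class-activation attention map for one view
#'
#' Weighted channel sum of the view's final feature map, using the head
#' weight block of that view as channel weights, rectified at zero,
#' bilinearly upsampled to the cropped-image resolution, and min-max
#' normalized to `[0, 1]`. Being a plain weighted sum of activations, the
#' map is first-order differentiable in the model parameters, so it can be
#' supervised by a pixel-level loss without second-order gradients.
#'
#' @param feature_map h x w x C post-ReLU feature map.
#' @param head_weights length-C weight block of the view (see
#'   [head_weights_for_view()]).
#' @param out_shape length-2 output (crop) resolution.
#' @return `out_shape` matrix in `[0, 1]` (all zeros if the rectified map
#'   is identically constant).
#' @export
cam_attention <- function(feature_map, head_weights, out_shape) {
  d <- dim(feature_map)
  if (length(head_weights) != d[3]) {
    stop("head weight block length ", length(head_weights),
         " does not match feature channels ", d[3])
  }
  m <- matrix(feature_map, d[1] * d[2], d[3]) %*% head_weights
  m <- relu(matrix(m, d[1], d[2]))
  up <- .bilinear_up(m, as.integer(out_shape[1]), as.integer(out_shape[2]))
  minmax_normalize(up)
}

#' Gradient-weighted class-activation map for one view
#'
#' Channel weights are the spatially averaged gradients of the
#' classification logit with respect to the feature map. For this
#' architecture (linear head on LSE-pooled features) the gradient is
#' available in closed form: `d logit / d A_k(i,j) = w_k * softmax_k(i,j)`
#' where the softmax is the LSE pooling weight field, so the averaged
#' weight is `w_k / (h*w)` - proportional to the head weights. The
#' resulting normalized map therefore coincides with [cam_attention()],
#' which is asserted in the test suite; the mode exists for visualization
#' parity and for backbones whose head is not linear.
#'
#' @param feature_map h x w x C post-ReLU feature map.
#' @param head_weights length-C head weight block of the view.
#' @param r LSE pooling sharpness used by the model.
#' @param out_shape length-2 output resolution.
#' @return List with the normalized `map` and the channel `weights` alpha.
#' @export
grad_cam_attention <- function(feature_map, head_weights, r, out_shape) {
  d <- dim(feature_map)
  sm <- lse_pool_weights(feature_map, r)           # (h*w) x C
  grad <- sweep(sm, 2L, head_weights, "*")         # d logit / d A
  alpha <- colMeans(grad)
  m <- matrix(feature_map, d[1] * d[2], d[3]) %*% alpha
  m <- relu(matrix(m, d[1], d[2]))
  up <- .bilinear_up(m, as.integer(out_shape[1]), as.integer(out_shape[2]))
  list(map = minmax_normalize(up), weights = alpha)
}

#' Intersection-over-union of an attention map and a lesion mask
#'
#' Quantifies how well the thresholded attention matches the annotated
#' lesion region.
#'
#' @param attention matrix in `[0, 1]`.
#' @param mask2d binary matrix of the same shape.
#' @param threshold attention binarization level (default 0.5).
#' @return IoU in `[0, 1]` (1 if both regions are empty).
#' @export
attention_mask_iou <- function(attention, mask2d, threshold = 0.5) {
  if (!identical(dim(attention), dim(mask2d))) stop("shape mismatch")
  a <- attention >= threshold
  b <- mask2d != 0
  uni <- sum(a | b)
  if (uni == 0) return(1)
  sum(a & b) / uni
}

#' Attention maps of a trained model on one sample
#'
#' Convenience wrapper: runs [forward()] and computes the per-view
#' attention map at the sample's image resolution.
#'
#' @param model a `mvattn_model`.
#' @param sample preprocessed multi-view sample.
#' @param mode `"cam"` (head-weight channel weighting) or `"grad_cam"`.
#' @return Named list of per-view attention matrices in `[0, 1]`.
#' @export
attention_maps <- function(model, sample, mode = c("cam", "grad_cam")) {
  mode <- match.arg(mode)
  fw <- forward(model, sample)
  out <- list()
  for (v in model$views) {
    hw <- head_weights_for_view(model, v)
    shape <- dim(sample$images[[v]])
    out[[v]] <- if (mode == "cam") {
      cam_attention(fw$fmaps[[v]], hw, shape)
    } else {
      grad_cam_attention(fw$fmaps[[v]], hw, model$r, shape)$map
    }
  }
  out
}
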
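#' Binary cross-entropy classification loss
#'
#' `-(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))` over a batch, with
#' probabilities clamped to `[eps, 1 - eps]` so the loss and its gradient
#' stay finite.
#'
#' @param labels batch of labels in {0, 1}.
#' @param probs batch of predicted probabilities.
#' @param eps clamping epsilon (default 1e-7).
#' @return Non-negative scalar.
#' @export
classification_loss <- function(labels, probs, eps = 1e-7) {
  if (length(labels) == 0) stop("empty batch")
  if (length(labels) != length(probs)) stop("length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be in {0, 1}")
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Attention (segmentation) supervision loss
#'
#' Mean squared error between the attention map and the binary label map
#' of the tumor region, averaged over pixels; for a batch (lists of maps)
#' the per-sample values are averaged. Implemented as a positive quantity.
#'
#' @param label_map binary matrix, or list of matrices for a batch.
#' @param attention matrix in `[0, 1]` of the same shape, or matching list.
#' @return Non-negative scalar.
#' @export
attention_loss <- function(label_map, attention) {
  if (is.list(label_map) != is.list(attention)) stop("shape mismatch")
  if (is.list(label_map)) {
    if (length(label_map) != length(attention)) stop("batch size mismatch")
    return(mean(mapply(attention_loss, label_map, attention)))
  }
  if (!identical(dim(label_map), dim(attention))) stop("shape mismatch")
  mean((label_map - attention)^2)
}

#' Combine the classification and per-view attention losses
#'
#' The per-view attention losses are summed (`Ls_all`) and added to the
#' classification loss with weight `lambda`:
#' `L = Lc + lambda * Ls_all`, default `lambda = 0.5`. Setting
#' `lambda = 0` recovers plain classification training.
#'
#' @param Lc classification loss.
#' @param Ls_sagittal,Ls_axial,Ls_coronal per-view attention losses
#'   (use 0 for absent views).
#' @param lambda attention weight (default 0.5).
#' @param N batch size the losses were averaged over (bookkeeping only).
#' @return A `loss_bundle` list: `Lc`, `Ls_sagittal`, `Ls_axial`,
#'   `Ls_coronal`, `Ls_all`, `L`, `N`.
#' @export
total_loss <- function(Lc, Ls_sagittal = 0, Ls_axial = 0, Ls_coronal = 0,
                       lambda = 0.5, N = NA_integer_) {
  vals <- c(Lc, Ls_sagittal, Ls_axial, Ls_coronal, lambda)
  if (!all(is.finite(vals))) stop("non-finite loss input")
  Ls_all <- Ls_sagittal + Ls_axial + Ls_coronal
  structure(list(Lc = Lc, Ls_sagittal = Ls_sagittal, Ls_axial = Ls_axial,
                 Ls_coronal = Ls_coronal, Ls_all = Ls_all,
                 L = Lc + lambda * Ls_all, N = N),
            class = "loss_bundle")
}
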
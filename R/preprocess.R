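#' Merge multiple lesion masks into one annotation
#'
#' Patients with several lesions are delineated lesion by lesion and the
#' delineations integrated into a single whole; this is the voxelwise
#' union.
#'
#' @param masks list of binary arrays of identical shape.
#' @return Binary array of the same shape.
#' @export
merge_lesions <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  d <- dim(masks[[1]])
  out <- array(0L, d)
  for (m in masks) {
    if (!identical(dim(m), d)) stop("mask shapes differ")
    check_binary_mask(m)
    out <- out | (m != 0)
  }
  array(as.integer(out), d)
}

#' Select the 2-D slice with maximal lesion area
#'
#' Views are stored so the third array axis is the out-of-plane (slice)
#' axis; the slice whose mask has the largest area is taken as the 2-D
#' image for that view, ties broken by the smallest slice index.
#'
#' @param volume 3-D intensity array.
#' @param mask binary 3-D array of the same shape; must be nonempty.
#' @return List with `image2d`, `mask2d` and the 1-based `slice_index`.
#' @export
select_slice <- function(volume, mask) {
  stopifnot(identical(dim(volume), dim(mask)))
  if (sum(mask) == 0) stop("mask is empty")
  areas <- apply(mask, 3L, sum)
  k <- which.max(areas)  # which.max returns the first maximum
  list(image2d = volume[, , k], mask2d = mask[, , k], slice_index = k)
}

#' Crop a square window centered on the lesion
#'
#' Crops `crop_size` x `crop_size` pixels with the lesion bounding-box
#' center (rounded down) at the window center, so background away from the
#' tumor region is discarded and all samples share one size. Parts of the
#' window outside the image are zero-padded; intensities inside are copied
#' untouched.
#'
#' @param image2d intensity matrix.
#' @param mask2d binary matrix of the same shape; must be nonempty.
#' @param crop_size window side in pixels (default 256).
#' @return List of class `cropped_sample`: `image2d`, `mask2d`
#'   (both `crop_size` square), and `offset` (0-based position of the
#'   window's first pixel in the source image).
#' @export
crop_centered <- function(image2d, mask2d, crop_size = 256) {
  stopifnot(identical(dim(image2d), dim(mask2d)), crop_size >= 1)
  if (sum(mask2d) == 0) stop("mask is empty")
  idx <- which(mask2d != 0, arr.ind = TRUE)
  bb_center <- floor((apply(idx, 2, min) + apply(idx, 2, max)) / 2)
  start <- bb_center - floor(crop_size / 2)  # 0-based window start
  img <- matrix(0, crop_size, crop_size)
  msk <- matrix(0L, crop_size, crop_size)
  src_r <- pmax(1L, start[1] + 1L):pmin(nrow(image2d), start[1] + crop_size)
  src_c <- pmax(1L, start[2] + 1L):pmin(ncol(image2d), start[2] + crop_size)
  if (length(src_r) > 0 && length(src_c) > 0 &&
      src_r[1] <= src_r[length(src_r)] && src_c[1] <= src_c[length(src_c)]) {
    dst_r <- src_r - start[1]
    dst_c <- src_c - start[2]
    img[dst_r, dst_c] <- image2d[src_r, src_c]
    msk[dst_r, dst_c] <- mask2d[src_r, src_c]
  }
  structure(list(image2d = img, mask2d = msk, offset = start),
            class = "cropped_sample")
}

#' Maximum tumor diameter in patient-space millimetres
#'
#' The maximum pairwise distance between mask voxel centers in the patient
#' coordinate system, measured on the sagittal annotation. Computed on the
#' convex hull of the voxel-center point cloud (the diameter of a point set
#' is attained between hull vertices).
#'
#' @param mask binary 3-D array; must be nonempty.
#' @param geom the mask grid's [volume_geometry()].
#' @return Scalar mm (0 for a single-voxel mask).
#' @export
tumor_diameter <- function(mask, geom) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty")
  if (nrow(idx) == 1) return(0)
  # the farthest pair is attained between convex-hull vertices, and every
  # hull vertex is a surface voxel (an interior voxel center is the
  # centroid of its six face-neighbors), so reduce to surface voxels first
  d <- dim(mask)
  padded <- array(0L, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  nb_sum <- padded[cbind(idx[, 1], idx[, 2] + 1L, idx[, 3] + 1L)] +
    padded[cbind(idx[, 1] + 2L, idx[, 2] + 1L, idx[, 3] + 1L)] +
    padded[cbind(idx[, 1] + 1L, idx[, 2], idx[, 3] + 1L)] +
    padded[cbind(idx[, 1] + 1L, idx[, 2] + 2L, idx[, 3] + 1L)] +
    padded[cbind(idx[, 1] + 1L, idx[, 2] + 1L, idx[, 3])] +
    padded[cbind(idx[, 1] + 1L, idx[, 2] + 1L, idx[, 3] + 2L)]
  surf <- idx[nb_sum < 6L, , drop = FALSE]
  pts <- voxel_to_patient(geom, surf - 1)
  max(stats::dist(pts))
}

#' Z-score normalize an image
#'
#' @param image2d intensity matrix.
#' @return Matrix with zero mean and unit variance (all-constant input
#'   maps to all zeros).
#' @export
normalize_intensity <- function(image2d) {
  s <- stats::sd(image2d)
  if (!is.finite(s) || s == 0) return(image2d * 0)
  (image2d - mean(image2d)) / s
}

#' Preprocess a phantom cohort into multi-view network samples
#'
#' For every patient: transfer the sagittal annotation onto the axial and
#' coronal grids through the patient coordinate system, pick the
#' maximal-lesion-area slice per view, z-score normalize the full slice,
#' and crop a lesion-centered square window. Normalization is computed on
#' the whole slice - where the lesion is a small part of the image - not
#' on the lesion-dominated crop, so it removes scanner gain and offset
#' without cancelling the lesion's own intensity contrast. Raw
#' (unnormalized) crops are retained for the radiomics arm.
#'
#' @param cohort list of patients from [generate_cohort()] /
#'   [read_cohort()].
#' @param crop_size window side in pixels (default 256; smaller values are
#'   appropriate for the phantom's field of view).
#' @return List of multi-view samples: `patient_id`, `label`, and per view
#'   `images` (normalized), `images_raw`, `masks`, `slice_index`.
#' @export
preprocess_cohort <- function(cohort, crop_size = 256) {
  lapply(cohort, function(p) {
    masks3d <- list(sagittal = p$sagittal_mask)
    for (v in c("axial", "coronal")) {
      masks3d[[v]] <- transfer_annotation(
        p$sagittal_mask, p$geometries$sagittal, p$geometries[[v]],
        dim(p$volumes[[v]]))
    }
    images <- list(); images_raw <- list(); masks <- list()
    slice_index <- list()
    for (v in c("sagittal", "axial", "coronal")) {
      sl <- select_slice(p$volumes[[v]], masks3d[[v]])
      cs <- crop_centered(sl$image2d, sl$mask2d, crop_size)
      cn <- crop_centered(normalize_intensity(sl$image2d), sl$mask2d,
                          crop_size)
      images_raw[[v]] <- cs$image2d
      images[[v]] <- cn$image2d
      masks[[v]] <- cs$mask2d
      slice_index[[v]] <- sl$slice_index
    }
    list(patient_id = p$patient_id, label = p$label, images = images,
         images_raw = images_raw, masks = masks, slice_index = slice_index)
  })
}
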
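#' Volume geometry in the patient coordinate system
#'
#' Describes how a 3-D voxel grid sits in the DICOM patient coordinate
#' system (millimetres). The convention mirrors the DICOM header fields:
#' `origin` is the patient-space position of the *center* of voxel
#' `(0, 0, 0)` (ImagePositionPatient), `row_direction` and
#' `column_direction` are the unit vectors along which the first (row) and
#' second (column) array indices advance (ImageOrientationPatient), and
#' `slice_direction` is the unit vector along the third index. Voxel
#' indices are 0-based and continuous: index `(i, j, k)` maps to
#' `origin + i * ps[1] * row + j * ps[2] * col + k * ss * slice`.
#'
#' @param origin numeric length-3, mm position of voxel (0,0,0) center.
#' @param row_direction,column_direction,slice_direction unit length-3
#'   direction cosines; row and column must be orthogonal.
#' @param pixel_spacing numeric length-2, mm per step along (row, column).
#' @param slice_spacing positive scalar, mm per step along the slice axis
#'   (DICOM SpacingBetweenSlices).
#' @return An object of class `volume_geometry`.
#' @examples
#' g <- volume_geometry(c(0, 0, 0))
#' voxel_to_patient(g, c(3, 4, 5))
#' @export
volume_geometry <- function(origin,
                            row_direction = c(1, 0, 0),
                            column_direction = c(0, 1, 0),
                            slice_direction = c(0, 0, 1),
                            pixel_spacing = c(1, 1),
                            slice_spacing = 1) {
  origin <- as.numeric(origin)
  row_direction <- as.numeric(row_direction)
  column_direction <- as.numeric(column_direction)
  slice_direction <- as.numeric(slice_direction)
  stopifnot(length(origin) == 3L, length(row_direction) == 3L,
            length(column_direction) == 3L, length(slice_direction) == 3L,
            length(pixel_spacing) == 2L, length(slice_spacing) == 1L)
  for (v in list(row_direction, column_direction, slice_direction)) {
    if (abs(sqrt(sum(v^2)) - 1) > 1e-6) {
      stop("direction vectors must be unit length (tolerance 1e-6)")
    }
  }
  if (abs(sum(row_direction * column_direction)) > 1e-6) {
    stop("row and column directions must be orthogonal (tolerance 1e-6)")
  }
  if (any(pixel_spacing <= 0) || slice_spacing <= 0) {
    stop("spacings must be positive")
  }
  structure(
    list(origin = origin, row_direction = row_direction,
         column_direction = column_direction,
         slice_direction = slice_direction,
         pixel_spacing = as.numeric(pixel_spacing),
         slice_spacing = as.numeric(slice_spacing)),
    class = "volume_geometry"
  )
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat("volume_geometry\n")
  cat("  origin        :", format(x$origin), "mm\n")
  cat("  row dir       :", format(x$row_direction), "\n")
  cat("  column dir    :", format(x$column_direction), "\n")
  cat("  slice dir     :", format(x$slice_direction), "\n")
  cat("  pixel spacing :", format(x$pixel_spacing), "mm\n")
  cat("  slice spacing :", format(x$slice_spacing), "mm\n")
  invisible(x)
}

#' 4x4 homogeneous voxel-to-patient affine of a geometry
#'
#' Columns 1..3 scale the unit index steps by the spacings and rotate them
#' into patient space; column 4 is the origin.
#'
#' @param geom a [volume_geometry()].
#' @return 4x4 numeric matrix `A` with `A %*% c(i, j, k, 1)` giving the
#'   patient-space position (mm, homogeneous).
#' @export
geometry_affine <- function(geom) {
  stopifnot(inherits(geom, "volume_geometry"))
  A <- diag(4)
  A[1:3, 1] <- geom$row_direction * geom$pixel_spacing[1]
  A[1:3, 2] <- geom$column_direction * geom$pixel_spacing[2]
  A[1:3, 3] <- geom$slice_direction * geom$slice_spacing
  A[1:3, 4] <- geom$origin
  A
}

as_coord_matrix <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3L)
    p
  } else {
    stopifnot(length(p) == 3L)
    matrix(as.numeric(p), nrow = 1L)
  }
}

#' Map continuous voxel indices to patient coordinates
#'
#' @param geom a [volume_geometry()].
#' @param ijk length-3 vector or n x 3 matrix of continuous 0-based voxel
#'   indices.
#' @return Patient-space mm coordinates, same shape as the input.
#' @export
voxel_to_patient <- function(geom, ijk) {
  stopifnot(inherits(geom, "volume_geometry"))
  m <- as_coord_matrix(ijk)
  M <- cbind(geom$row_direction * geom$pixel_spacing[1],
             geom$column_direction * geom$pixel_spacing[2],
             geom$slice_direction * geom$slice_spacing)
  out <- m %*% t(M)
  out <- sweep(out, 2L, geom$origin, "+")
  if (!is.matrix(ijk)) out <- drop(out)
  out
}

#' Map patient coordinates to continuous voxel indices
#'
#' Exact inverse of [voxel_to_patient()]. Degenerate geometries whose
#' direction vectors do not span 3-space are rejected.
#'
#' @param geom a [volume_geometry()].
#' @param xyz length-3 vector or n x 3 matrix of patient-space mm points.
#' @return Continuous 0-based voxel indices, same shape as the input.
#' @export
patient_to_voxel <- function(geom, xyz) {
  stopifnot(inherits(geom, "volume_geometry"))
  m <- as_coord_matrix(xyz)
  M <- cbind(geom$row_direction * geom$pixel_spacing[1],
             geom$column_direction * geom$pixel_spacing[2],
             geom$slice_direction * geom$slice_spacing)
  if (abs(det(M)) < 1e-12) {
    stop("singular geometry: direction vectors do not span 3-D space")
  }
  rel <- sweep(m, 2L, geom$origin, "-")
  out <- t(solve(M, t(rel)))
  if (!is.matrix(xyz)) out <- drop(out)
  out
}

#' Transfer a binary annotation between two view grids
#'
#' Realizes the cross-view annotation transfer: every destination voxel
#' center is mapped through the shared patient coordinate system into the
#' source grid, the source mask is sampled there by trilinear interpolation
#' of the binary field (the "linear interpolation" that keeps transferred
#' annotations continuous across slice gaps), and the interpolated value is
#' binarized at 0.5. Sampling is pull-based (destination-driven), so
#' anisotropic spacings cannot leave holes.
#'
#' @param src_mask 3-D array with values in {0,1}; must be nonempty.
#' @param src_geom,dst_geom [volume_geometry()] of the source and
#'   destination grids.
#' @param dst_shape integer length-3 destination array dimensions.
#' @param threshold binarization level applied to the interpolated field.
#' @return Binary 3-D array of dimension `dst_shape`. If the source lesion
#'   does not intersect the destination field of view, an empty mask is
#'   returned with a warning.
#' @export
transfer_annotation <- function(src_mask, src_geom, dst_geom, dst_shape,
                                threshold = 0.5) {
  stopifnot(length(dim(src_mask)) == 3L, length(dst_shape) == 3L)
  check_binary_mask(src_mask)
  if (sum(src_mask) == 0) stop("source mask is empty")
  dst_shape <- as.integer(dst_shape)
  ijk <- as.matrix(expand.grid(i = seq_len(dst_shape[1]) - 1L,
                               j = seq_len(dst_shape[2]) - 1L,
                               k = seq_len(dst_shape[3]) - 1L))
  xyz <- voxel_to_patient(dst_geom, ijk)
  src_ijk <- patient_to_voxel(src_geom, xyz)
  vals <- .trilinear_sample(array(as.double(src_mask), dim(src_mask)),
                            src_ijk, 0)
  out <- array(as.integer(vals >= threshold), dim = dst_shape)
  if (sum(out) == 0) {
    warning("transferred annotation is empty: lesion does not overlap the ",
            "destination field of view")
  }
  out
}

#' Patient-space centroid of a binary mask
#'
#' @param mask binary 3-D array.
#' @param geom the mask grid's [volume_geometry()].
#' @return Length-3 mm coordinates of the mean voxel-center position.
#' @export
mask_centroid_patient <- function(mask, geom) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty")
  colMeans(voxel_to_patient(geom, idx - 1))
}

#' Physical volume of a binary mask in cubic millimetres
#'
#' @param mask binary 3-D array.
#' @param geom the mask grid's [volume_geometry()].
#' @return Scalar mm^3 (voxel count times voxel volume).
#' @export
mask_volume_mm3 <- function(mask, geom) {
  sum(mask != 0) * prod(geom$pixel_spacing) * geom$slice_spacing
}

check_binary_mask <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop("mask values must be in {0, 1}")
  invisible(TRUE)
}

#' Serialize a geometry to DICOM-style sidecar fields
#'
#' The sidecar mirrors the DICOM header: `ImagePositionPatient` (origin),
#' `ImageOrientationPatient` (row then column direction cosines, 6 values),
#' `PixelSpacing`, `SpacingBetweenSlices`, plus `SliceDirection` so the
#' full 3-D affine is reconstructible without a cross product convention.
#'
#' @param geom a [volume_geometry()].
#' @return Named list of sidecar fields.
#' @export
geometry_to_sidecar <- function(geom) {
  stopifnot(inherits(geom, "volume_geometry"))
  list(
    ImagePositionPatient = geom$origin,
    ImageOrientationPatient = c(geom$row_direction, geom$column_direction),
    PixelSpacing = geom$pixel_spacing,
    SpacingBetweenSlices = geom$slice_spacing,
    SliceDirection = geom$slice_direction
  )
}

#' Reconstruct a geometry from sidecar fields
#'
#' Inverse of [geometry_to_sidecar()]. If `SliceDirection` is absent the
#' right-handed cross product of the row and column directions is used.
#'
#' @param sidecar named list as produced by [geometry_to_sidecar()] (or
#'   parsed from a JSON sidecar file).
#' @return A [volume_geometry()].
#' @export
sidecar_to_geometry <- function(sidecar) {
  iop <- as.numeric(sidecar$ImageOrientationPatient)
  stopifnot(length(iop) == 6L)
  rd <- iop[1:3]
  cd <- iop[4:6]
  sd <- sidecar$SliceDirection
  if (is.null(sd)) {
    sd <- c(rd[2] * cd[3] - rd[3] * cd[2],
            rd[3] * cd[1] - rd[1] * cd[3],
            rd[1] * cd[2] - rd[2] * cd[1])
  }
  volume_geometry(
    origin = as.numeric(sidecar$ImagePositionPatient),
    row_direction = rd, column_direction = cd,
    slice_direction = as.numeric(sd),
    pixel_spacing = as.numeric(sidecar$PixelSpacing),
    slice_spacing = as.numeric(sidecar$SpacingBetweenSlices)
  )
}

#' Write / read a JSON geometry sidecar
#'
#' @param geom a [volume_geometry()].
#' @param path file path for the JSON sidecar.
#' @return `write_geometry_json()` returns `path` invisibly;
#'   `read_geometry_json()` returns a [volume_geometry()].
#' @export
write_geometry_json <- function(geom, path) {
  jsonlite::write_json(geometry_to_sidecar(geom), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  sidecar_to_geometry(jsonlite::read_json(path, simplifyVector = TRUE))
}
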
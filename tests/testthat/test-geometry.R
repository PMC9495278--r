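test_that("voxel_to_patient implements the DICOM affine", {
  g_id <- volume_geometry(c(0, 0, 0))
  expect_equal(voxel_to_patient(g_id, c(3, 4, 5)), c(3, 4, 5))

  g <- volume_geometry(c(10, 0, 0), pixel_spacing = c(0.5, 0.5),
                       slice_spacing = 2)
  expect_equal(voxel_to_patient(g, c(2, 2, 1)), c(11, 1, 2))

  # permuted axes match the 4x4 homogeneous-matrix oracle
  gp <- volume_geometry(c(1, -2, 3),
                        row_direction = c(0, 0, 1),
                        column_direction = c(1, 0, 0),
                        slice_direction = c(0, 1, 0),
                        pixel_spacing = c(0.7, 1.3), slice_spacing = 2.5)
  A <- geometry_affine(gp)
  for (p in list(c(0, 0, 0), c(5, 2, 9), c(1.5, -0.25, 3.75))) {
    expect_equal(voxel_to_patient(gp, p),
                 as.numeric(A %*% c(p, 1))[1:3], tolerance = 1e-12)
  }
})

test_that("patient_to_voxel inverts voxel_to_patient to 1e-9", {
  gp <- volume_geometry(c(4, 5, -6),
                        row_direction = c(0, 1, 0),
                        column_direction = c(0, 0, -1),
                        slice_direction = c(1, 0, 0),
                        pixel_spacing = c(0.8, 1.1), slice_spacing = 3)
  set.seed(1)
  pts <- matrix(runif(300, -20, 80), ncol = 3)
  round_trip <- patient_to_voxel(gp, voxel_to_patient(gp, pts))
  expect_lt(max(abs(round_trip - pts)), 1e-9)

  g <- volume_geometry(c(10, 0, 0), pixel_spacing = c(0.5, 0.5),
                       slice_spacing = 2)
  expect_equal(patient_to_voxel(g, c(11, 1, 2)), c(2, 2, 1))
})

test_that("geometry validation rejects malformed inputs", {
  expect_error(volume_geometry(c(0, 0, 0), row_direction = c(1, 1, 0)),
               "unit")
  expect_error(volume_geometry(c(0, 0, 0),
                               column_direction = c(1, 0, 0)),
               "orthogonal")
  expect_error(volume_geometry(c(0, 0, 0), pixel_spacing = c(0, 1)),
               "positive")
})

test_that("annotation transfer onto the identical grid is the identity", {
  mask <- random_blob_mask(c(20, 18, 16), seed = 5)
  g <- volume_geometry(c(0.3, -1, 2), pixel_spacing = c(1, 1.2),
                       slice_spacing = 2)
  expect_identical(transfer_annotation(mask, g, g, dim(mask)), mask)
})

test_that("transfer conserves volume under grid refinement and centroids across grids", {
  for (seed in 1:6) {
    mask <- random_blob_mask(c(24, 24, 20), seed = seed)
    src <- volume_geometry(c(0, 0, 0), pixel_spacing = c(1, 1),
                           slice_spacing = 2)
    # destination: same FOV at half spacing
    fine <- volume_geometry(c(-0.25, -0.25, -0.5),
                            pixel_spacing = c(0.5, 0.5), slice_spacing = 1)
    tf <- transfer_annotation(mask, src, fine, c(48, 48, 40))
    v_src <- mask_volume_mm3(mask, src)
    v_dst <- mask_volume_mm3(tf, fine)
    expect_lt(abs(v_dst - v_src) / v_src, 0.10)

    # rotated/offset destination grid: patient-space centroid agreement
    dst <- volume_geometry(c(23, 1, -0.5),
                           row_direction = c(0, 0, 1),
                           column_direction = c(0, 1, 0),
                           slice_direction = c(-1, 0, 0),
                           pixel_spacing = c(0.9, 1.1), slice_spacing = 1.5)
    tf2 <- transfer_annotation(mask, src, dst, c(48, 24, 18))
    c_src <- mask_centroid_patient(mask, src)
    c_dst <- mask_centroid_patient(tf2, dst)
    tol <- max(src$pixel_spacing, src$slice_spacing,
               dst$pixel_spacing, dst$slice_spacing)
    expect_lt(sqrt(sum((c_src - c_dst)^2)), tol)
  }
})

test_that("transfer matches nearest-voxel sampling in lesion interiors", {
  mask <- random_blob_mask(c(24, 24, 20), seed = 9)
  src <- volume_geometry(c(0, 0, 0), slice_spacing = 1)
  dst <- volume_geometry(c(0.2, 0.1, -0.3), pixel_spacing = c(0.8, 0.8),
                         slice_spacing = 1.1)
  dst_shape <- c(30, 30, 19)
  tf <- transfer_annotation(mask, src, dst, dst_shape)
  ijk <- as.matrix(expand.grid(i = seq_len(dst_shape[1]) - 1,
                               j = seq_len(dst_shape[2]) - 1,
                               k = seq_len(dst_shape[3]) - 1))
  src_ijk <- patient_to_voxel(src, voxel_to_patient(dst, ijk))
  nn <- round(src_ijk)
  inside <- nn[, 1] >= 0 & nn[, 1] < 24 & nn[, 2] >= 0 & nn[, 2] < 24 &
    nn[, 3] >= 0 & nn[, 3] < 20
  oracle <- rep(0L, nrow(nn))
  oracle[inside] <- mask[nn[inside, , drop = FALSE] + 1]
  # interior = all 26-ish neighbourhood sampled positions agree; here we
  # only require agreement away from the lesion boundary, where the
  # interpolated field is flat at 0 or 1
  vals <- mvlesion:::.trilinear_sample(array(as.double(mask), dim(mask)),
                                       src_ijk, 0)
  interior <- vals <= 0.01 | vals >= 0.99
  expect_true(all(as.integer(tf)[interior] == oracle[interior]))
  expect_true(all(tf %in% c(0L, 1L)))
})

test_that("transfer errors and warnings are explicit", {
  g <- volume_geometry(c(0, 0, 0))
  empty <- array(0L, c(4, 4, 4))
  expect_error(transfer_annotation(empty, g, g, c(4, 4, 4)), "empty")
  mask <- array(0L, c(4, 4, 4)); mask[2, 2, 2] <- 1L
  far <- volume_geometry(c(1000, 1000, 1000))
  expect_warning(out <- transfer_annotation(mask, g, far, c(4, 4, 4)),
                 "overlap")
  expect_equal(sum(out), 0)
})

test_that("geometry JSON sidecar reconstructs the same affine", {
  g <- volume_geometry(c(3, -4, 5.5),
                       row_direction = c(0, 0, -1),
                       column_direction = c(1, 0, 0),
                       slice_direction = c(0, 1, 0),
                       pixel_spacing = c(0.8, 0.8), slice_spacing = 2)
  path <- tempfile(fileext = ".json")
  write_geometry_json(g, path)
  g2 <- read_geometry_json(path)
  expect_equal(geometry_affine(g2), geometry_affine(g), tolerance = 1e-12)
  # sidecar carries the DICOM field names
  sc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_named(sc, c("ImagePositionPatient", "ImageOrientationPatient",
                     "PixelSpacing", "SpacingBetweenSlices",
                     "SliceDirection"), ignore.order = TRUE)
  expect_length(sc$ImageOrientationPatient, 6)
})
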
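#' Specification of a synthetic tri-view phantom cohort
#'
#' Defines the statistical structure of a simulated cohort: two classes at
#' a fixed prevalence, one to a few smooth ellipsoidal lesions per patient
#' embedded in a vertebra-like periodic background, class-dependent lesion
#' texture as the only class signal (lesion size and location distributions
#' are identical across classes), and three views that are resampled
#' renderings of one underlying patient-space scene, each with its own
#' spacing, axis permutation and origin so that cross-view annotation
#' transfer is nontrivial.
#'
#' `volume_shape` is the sagittal grid (rows along the patient y axis at
#' 1 mm, columns along z at 1 mm, slices along x at 2 mm); the axial and
#' coronal grids are derived to cover the same field of view with their
#' own spacings (coronal in-plane 0.8 mm, one flipped axis).
#'
#' @param n_patients number of patients.
#' @param prevalence positive-class probability, in (0, 1). The cohort
#'   contains exactly `round(n_patients * prevalence)` positives.
#' @param volume_shape integer length-3 sagittal grid dimensions.
#' @param lesion_count_range integer pair, inclusive range of lesions per
#'   patient.
#' @param lesion_radius_range mm pair, range of the lesion base radius.
#' @param lesion_spread mm; additional lesions of a multi-lesion patient
#'   are placed within this distance of the first (lesions cluster in
#'   neighbouring vertebrae), keeping the merged annotation compact.
#' @param texture_effect non-negative class-separation strength: amplitude
#'   of the non-negative band-limited texture ripple added inside positive
#'   patients' lesions (0 makes the classes exchangeable).
#' @param noise_sd per-view additive Gaussian noise, intensity units.
#' @param lesion_contrast intensity added inside every lesion (both
#'   classes), emulating contrast enhancement.
#' @param seed integer; the same seed and spec give a bit-identical cohort.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(n_patients = 4, seed = 1)
#' cohort <- generate_cohort(spec)
#' cohort[[1]]$label
#' @export
phantom_spec <- function(n_patients, prevalence = 0.3,
                         volume_shape = c(64, 64, 32),
                         lesion_count_range = c(1, 3),
                         lesion_radius_range = c(3, 6),
                         lesion_spread = 8,
                         texture_effect = 60, noise_sd = 10,
                         lesion_contrast = 80, seed = 1) {
  stopifnot(n_patients >= 1, length(volume_shape) == 3L,
            length(lesion_count_range) == 2L,
            length(lesion_radius_range) == 2L,
            lesion_count_range[1] >= 1,
            lesion_count_range[1] <= lesion_count_range[2],
            lesion_radius_range[1] > 0,
            lesion_radius_range[1] <= lesion_radius_range[2],
            texture_effect >= 0, noise_sd >= 0, lesion_contrast >= 0)
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly inside (0, 1)")
  }
  fov <- c(2 * volume_shape[3], volume_shape[1], volume_shape[2])
  # largest semi-axis incl. per-axis jitter (x1.25) and smooth edge must fit
  # inside the central placement region of the field of view
  if (lesion_radius_range[2] * 1.25 + 2 > min(fov) / 4) {
    stop("lesions of the requested radius cannot fit inside the volume")
  }
  structure(
    list(n_patients = as.integer(n_patients), prevalence = prevalence,
         volume_shape = as.integer(volume_shape),
         lesion_count_range = as.integer(lesion_count_range),
         lesion_radius_range = as.numeric(lesion_radius_range),
         lesion_spread = as.numeric(lesion_spread),
         texture_effect = texture_effect, noise_sd = noise_sd,
         lesion_contrast = lesion_contrast, seed = as.integer(seed),
         fov = fov),
    class = "phantom_spec"
  )
}

# Run code with a private RNG stream, restoring the caller's state.
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Per-view grid geometries of the phantom
#'
#' Each view has a distinct axis permutation and spacing: sagittal rows
#' advance along patient y and slices along x; axial rows along x, slices
#' along z; coronal rows along -z (flipped axis) at 0.8 mm in-plane, slices
#' along y. Slice spacing is 2 mm everywhere (anisotropic, as in clinical
#' acquisitions). `jitter` displaces each view's origin independently so
#' that grids are not trivially aligned.
#'
#' @param spec a [phantom_spec()].
#' @param jitter length-3 list of per-view mm origin offsets (defaults 0).
#' @return Named list with, per view, `geom` ([volume_geometry()]) and
#'   `shape` (grid dimensions).
#' @export
phantom_view_grids <- function(spec, jitter = NULL) {
  fov <- spec$fov
  if (is.null(jitter)) {
    jitter <- list(sagittal = c(0, 0, 0), axial = c(0, 0, 0),
                   coronal = c(0, 0, 0))
  }
  cor_n <- ceiling(fov[3] / 0.8)
  list(
    sagittal = list(
      geom = volume_geometry(
        origin = c(1, 0.5, 0.5) + jitter$sagittal,
        row_direction = c(0, 1, 0), column_direction = c(0, 0, 1),
        slice_direction = c(1, 0, 0),
        pixel_spacing = c(1, 1), slice_spacing = 2),
      shape = spec$volume_shape),
    axial = list(
      geom = volume_geometry(
        origin = c(0.5, 0.5, 1) + jitter$axial,
        row_direction = c(1, 0, 0), column_direction = c(0, 1, 0),
        slice_direction = c(0, 0, 1),
        pixel_spacing = c(1, 1), slice_spacing = 2),
      shape = c(ceiling(fov[1]), ceiling(fov[2]), floor(fov[3] / 2))),
    coronal = list(
      geom = volume_geometry(
        origin = c(0.4, 1, fov[3] - 0.4) + jitter$coronal,
        row_direction = c(0, 0, -1), column_direction = c(1, 0, 0),
        slice_direction = c(0, 1, 0),
        pixel_spacing = c(0.8, 0.8), slice_spacing = 2),
      shape = c(cor_n, ceiling(fov[1] / 0.8), floor(fov[2] / 2)))
  )
}

# Evaluate the analytic patient-space scene at an n x 3 matrix of mm points.
# The scene is resolution-free, so all three views render the same anatomy.
eval_scene <- function(xyz, scene, spec) {
  fov <- spec$fov
  cx <- fov[1] / 2
  cy <- fov[2] / 2
  colprof <- exp(-((xyz[, 1] - cx)^2 + (xyz[, 2] - cy)^2) /
                   (2 * (min(fov[1:2]) / 5)^2))
  val <- 60 + 50 * colprof * (0.55 + 0.45 * cos(2 * pi * xyz[, 3] / 14))
  for (les in scene$lesions) {
    rel <- sweep(xyz, 2L, les$center, "-")
    d <- sqrt((rel[, 1] / les$semiaxes[1])^2 +
              (rel[, 2] / les$semiaxes[2])^2 +
              (rel[, 3] / les$semiaxes[3])^2)
    w <- pmin(1, pmax(0, (1 - d) / 0.25))
    inside <- w > 0
    if (!any(inside)) next
    add <- rep(spec$lesion_contrast, sum(inside))
    if (les$texture_amp > 0) {
      # class texture: a steady enhancement component plus a band-limited
      # ripple; the 0.6/0.4 split keeps the per-lesion texture dose stable
      # while leaving visible spatial heterogeneity
      ph <- rel[inside, , drop = FALSE] %*% t(les$tex_k)
      ripple <- rowMeans(cos(sweep(ph, 2L, les$tex_phase, "+")))
      add <- add + les$texture_amp * (0.6 + 0.4 * ripple)
    }
    val[inside] <- val[inside] + w[inside] * add
  }
  val
}

# Analytic lesion membership (at the half-height of the smooth edge).
scene_mask_values <- function(xyz, scene) {
  m <- rep(0L, nrow(xyz))
  for (les in scene$lesions) {
    rel <- sweep(xyz, 2L, les$center, "-")
    d <- sqrt((rel[, 1] / les$semiaxes[1])^2 +
              (rel[, 2] / les$semiaxes[2])^2 +
              (rel[, 3] / les$semiaxes[3])^2)
    m[d <= 0.875] <- 1L
  }
  m
}

grid_coords <- function(geom, shape) {
  ijk <- as.matrix(expand.grid(i = seq_len(shape[1]) - 1L,
                               j = seq_len(shape[2]) - 1L,
                               k = seq_len(shape[3]) - 1L))
  voxel_to_patient(geom, ijk)
}

# Draw one patient's scene (labels fixed upstream); RNG state is the
# caller's responsibility.
draw_patient_scene <- function(spec, label) {
  fov <- spec$fov
  n_les <- sample(seq(spec$lesion_count_range[1],
                      spec$lesion_count_range[2]), 1L)
  lesions <- vector("list", n_les)
  first_center <- NULL
  for (l in seq_len(n_les)) {
    r <- stats::runif(1, spec$lesion_radius_range[1],
                      spec$lesion_radius_range[2])
    semi <- r * stats::runif(3, 0.8, 1.25)
    margin <- max(semi) + 2
    if (l == 1) {
      center <- c(
        stats::runif(1, fov[1] / 2 - fov[1] / 6, fov[1] / 2 + fov[1] / 6),
        stats::runif(1, fov[2] / 2 - fov[2] / 6, fov[2] / 2 + fov[2] / 6),
        stats::runif(1, margin, fov[3] - margin)
      )
      first_center <- center
    } else {
      # additional lesions cluster near the first (adjacent vertebrae), so
      # the merged annotation stays coverable by a lesion-centered crop
      center <- first_center + stats::runif(3, -spec$lesion_spread,
                                            spec$lesion_spread)
      center <- pmin(pmax(center, margin), fov - margin)
    }
    n_comp <- 6L
    lam <- stats::runif(n_comp, 3, 8)
    dirs <- matrix(stats::rnorm(3 * n_comp), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    lesions[[l]] <- list(
      center = center, semiaxes = semi,
      texture_amp = if (label == 1) spec$texture_effect else 0,
      tex_k = dirs * (2 * pi / lam),
      tex_phase = stats::runif(n_comp, 0, 2 * pi)
    )
  }
  list(lesions = lesions)
}

#' Generate a synthetic tri-view phantom cohort
#'
#' Renders, for every patient, the three view volumes from one shared
#' patient-space scene plus the sagittal lesion mask. Masks for the axial
#' and coronal views are deliberately *not* emitted: they must be produced
#' by [transfer_annotation()], exactly as a sagittal-only clinical
#' annotation would be.
#'
#' @param spec a [phantom_spec()].
#' @return List of patients; each has `patient_id`, `label` (0/1),
#'   `volumes` and `geometries` (named by view), `sagittal_mask`, and the
#'   generating `scene` (lesion centers/axes, useful for oracles).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_patients
  with_local_seed(spec$seed, {
    n_pos <- round(n * spec$prevalence)
    labels <- integer(n)
    labels[sample.int(n, n_pos)] <- 1L
    pat_seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      set.seed(pat_seeds[i])
      scene <- draw_patient_scene(spec, labels[i])
      jitter <- list(sagittal = stats::runif(3, -0.5, 0.5),
                     axial = stats::runif(3, -0.5, 0.5),
                     coronal = stats::runif(3, -0.5, 0.5))
      grids <- phantom_view_grids(spec, jitter)
      volumes <- list()
      geometries <- list()
      for (v in names(grids)) {
        xyz <- grid_coords(grids[[v]]$geom, grids[[v]]$shape)
        vals <- eval_scene(xyz, scene, spec) +
          stats::rnorm(nrow(xyz), 0, spec$noise_sd)
        volumes[[v]] <- array(vals, grids[[v]]$shape)
        geometries[[v]] <- grids[[v]]$geom
      }
      sag <- grids$sagittal
      mask <- array(scene_mask_values(grid_coords(sag$geom, sag$shape),
                                      scene), sag$shape)
      stopifnot(sum(mask) > 0)
      list(patient_id = sprintf("P%04d", i), label = labels[i],
           volumes = volumes, geometries = geometries,
           sagittal_mask = mask, scene = scene)
    })
  })
}

#' Write a phantom cohort to disk
#'
#' Emits, per patient, one NIfTI volume and one JSON geometry sidecar per
#' view, the sagittal mask as NIfTI, and a cohort manifest CSV
#' (patient_id, label, relative file paths). Read-back through
#' [read_cohort()] reproduces every array exactly.
#'
#' @param cohort output of [generate_cohort()].
#' @param directory writable output directory (created if needed).
#' @return Path of the manifest CSV.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  views <- c("sagittal", "axial", "coronal")
  rows <- lapply(cohort, function(p) {
    row <- list(patient_id = p$patient_id, label = p$label)
    for (v in views) {
      vol_file <- paste0(p$patient_id, "_", v, ".nii.gz")
      geom_file <- paste0(p$patient_id, "_", v, "_geom.json")
      ok <- try({
        RNifti::writeNifti(RNifti::asNifti(p$volumes[[v]]),
                           file.path(directory, vol_file))
        write_geometry_json(p$geometries[[v]],
                            file.path(directory, geom_file))
      }, silent = TRUE)
      if (inherits(ok, "try-error")) {
        stop("failed to write ", file.path(directory, vol_file))
      }
      row[[paste0(v, "_volume")]] <- vol_file
      row[[paste0(v, "_geometry")]] <- geom_file
    }
    mask_file <- paste0(p$patient_id, "_sagittal_mask.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(p$sagittal_mask),
                       file.path(directory, mask_file))
    row$sagittal_mask <- mask_file
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(directory, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  manifest_path
}

#' Read a cohort back from a manifest
#'
#' @param manifest_path path to a manifest CSV written by [write_cohort()].
#' @return Cohort list in the layout of [generate_cohort()] (without the
#'   generating `scene`, which is not serialized).
#' @export
read_cohort <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  views <- c("sagittal", "axial", "coronal")
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    volumes <- list()
    geometries <- list()
    for (v in views) {
      vol <- RNifti::readNifti(file.path(base, row[[paste0(v, "_volume")]]))
      volumes[[v]] <- array(as.numeric(vol), dim(vol))
      geometries[[v]] <-
        read_geometry_json(file.path(base, row[[paste0(v, "_geometry")]]))
    }
    msk <- RNifti::readNifti(file.path(base, row$sagittal_mask))
    list(patient_id = row$patient_id, label = as.integer(row$label),
         volumes = volumes, geometries = geometries,
         sagittal_mask = array(as.integer(msk), dim(msk)))
  })
}
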
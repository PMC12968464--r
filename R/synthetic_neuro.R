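#' Volume grid geometry
#'
#' @param shape Integer vector (nx, ny, nz), default `c(20, 20, 16)`.
#' @param voxel_size_mm Isotropic voxel size (default 3 mm).
#' @param tr_s Volume acquisition time (default 1.056 s).
#' @param n_volumes Number of volumes.
#' @return Object of class `volume_grid`.
#' @export
volume_grid <- function(shape = c(20L, 20L, 16L), voxel_size_mm = 3,
                        tr_s = 1.056, n_volumes = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("shape must be three positive integers", call. = FALSE)
  }
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be > 0", call. = FALSE)
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm, tr_s = tr_s,
                 n_volumes = n_volumes),
            class = "volume_grid")
}

# k nearest voxels to a center, as a logical mask (gives exact voxel counts)
nearest_voxel_mask <- function(shape, center, n_voxels, within = NULL) {
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  ord <- order(d2, g$x, g$y, g$z)
  if (!is.null(within)) ord <- ord[within[ord]]
  if (length(ord) < n_voxels) stop("ROI exceeds available voxels", call. = FALSE)
  m <- array(FALSE, shape)
  m[ord[seq_len(n_voxels)]] <- TRUE
  m
}

#' Build a synthetic brain mask and disjoint ellipsoid-like ROIs
#'
#' Creates a desk-scale grid with a brain mask (an inscribed ellipsoid) and
#' named disjoint regions of interest, each the set of `roi_voxels` voxels
#' nearest a fixed center inside the brain. The default four regions stand in
#' for auditory cortex, hippocampus, inferior frontal gyrus and posterior
#' cingulate; all geometry is synthetic.
#'
#' @param shape Grid shape (default `c(20, 20, 16)`).
#' @param voxel_size_mm Voxel size (default 3 mm).
#' @param roi_voxels Named integer vector of ROI sizes; names become ROI
#'   names. Default four ROIs of 33 voxels.
#' @return List with `grid` ([volume_grid()]), `brain` (logical 3D) and
#'   `rois` (named list of logical 3D masks).
#' @export
make_grid_and_rois <- function(shape = c(20L, 20L, 16L), voxel_size_mm = 3,
                               roi_voxels = c(auditory = 33L, hippocampus = 33L,
                                              ifg = 33L, cingulate = 33L)) {
  grid <- volume_grid(shape, voxel_size_mm)
  cx <- (shape + 1) / 2
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  ell <- ((g$x - cx[1]) / (0.48 * shape[1]))^2 +
    ((g$y - cx[2]) / (0.48 * shape[2]))^2 +
    ((g$z - cx[3]) / (0.48 * shape[3]))^2
  brain <- array(ell <= 1, shape)
  # fixed fractional centers spread through the volume
  centers <- list(c(0.30, 0.30, 0.40), c(0.70, 0.30, 0.55),
                  c(0.30, 0.70, 0.55), c(0.70, 0.70, 0.40),
                  c(0.50, 0.50, 0.70), c(0.50, 0.30, 0.70))
  if (length(roi_voxels) > length(centers)) {
    stop("at most 6 ROIs supported", call. = FALSE)
  }
  avail <- brain
  rois <- list()
  for (i in seq_along(roi_voxels)) {
    ctr <- 1 + (shape - 1) * centers[[i]]
    m <- nearest_voxel_mask(shape, ctr, roi_voxels[i], within = avail)
    rois[[names(roi_voxels)[i]]] <- m
    avail <- avail & !m   # keep ROIs disjoint
  }
  list(grid = grid, brain = brain, rois = rois)
}

#' Effect specification for the synthetic BOLD generator
#'
#' Describes what is planted in the simulated data: per-ROI amplitudes for the
#' condition boxcars and the density parametric modulator, a per-ROI amplitude
#' for a multivoxel density pattern that is shared across subjects (required
#' for across-participant decoding), and the noise model.
#'
#' @param univariate_betas Named list: per ROI, a named numeric vector over
#'   regressors (`MA`, `MP`, `NA`, `NP`, `density`). Omitted entries are 0.
#' @param pattern_amplitude Named numeric vector: per ROI, the amplitude of
#'   the planted multivoxel low-vs-high density pattern (0 = none).
#' @param ar1 AR(1) coefficient of the noise (default 0.3).
#' @param noise_sd White-noise innovation SD (default 1).
#' @param drift_amplitude Amplitude of low-frequency cosine drift (default 1).
#' @param nuisance_leak Weight with which motion/respiration series leak into
#'   the data (default 0.3).
#' @param subject_sigma Between-subject SD on univariate amplitudes
#'   (default 0.2).
#' @param pattern_sigma Between-subject relative SD of the multivoxel pattern
#'   amplitude (default 0.1).
#' @param pattern_subject_sigma Relative SD of each subject's private
#'   voxelwise perturbation of the shared pattern (default 1): subjects
#'   share the voxel-level density code but express it with individual
#'   idiosyncrasy, as across-participant decoding of real cohorts assumes.
#' @return List of class `effect_spec`.
#' @export
effect_spec <- function(univariate_betas = list(),
                        pattern_amplitude = numeric(0),
                        ar1 = 0.3, noise_sd = 1, drift_amplitude = 1,
                        nuisance_leak = 0.3, subject_sigma = 0.2,
                        pattern_sigma = 0.1, pattern_subject_sigma = 1) {
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (abs(ar1) >= 1) stop("ar1 must lie in (-1, 1)", call. = FALSE)
  structure(list(univariate_betas = univariate_betas,
                 pattern_amplitude = pattern_amplitude,
                 ar1 = ar1, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 nuisance_leak = nuisance_leak,
                 subject_sigma = subject_sigma,
                 pattern_sigma = pattern_sigma,
                 pattern_subject_sigma = pattern_subject_sigma),
            class = "effect_spec")
}

# AR(1) noise, one column per voxel
ar1_noise <- function(n, v, rho, sd) {
  eps <- matrix(stats::rnorm(n * v, 0, sd), n, v)
  if (abs(rho) < 1e-12) return(eps)
  out <- stats::filter(eps, rho, method = "recursive")
  matrix(out, n, v)
}

make_nuisance <- function(n_volumes, tr_s) {
  t <- seq_len(n_volumes) * tr_s
  motion <- sapply(seq_len(6), function(k) {
    cumsum(stats::rnorm(n_volumes, 0, 0.02)) +
      0.1 * sin(2 * pi * t / (60 + 10 * k))
  })
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  resp <- sin(2 * pi * 0.25 * t + stats::runif(1, 0, 2 * pi))
  cbind(motion, respiration = resp)
}

# density label series (+1 high / -1 low) convolved with the HRF, per volume
label_regressor <- function(events, scale, n_volumes, tr_s) {
  ev <- events[events$event_type == "adjust_stack" &
                 !is.na(events$density_level), ]
  lab <- ifelse(density_split(scale, ev$density_level) == "high", 1, -1)
  hrf_regressor(ev$onset, ev$duration, lab, n_volumes, tr_s)
}

#' Generate one subject's synthetic 4D BOLD dataset
#'
#' The data are a sum of (i) HRF-convolved condition boxcars and the centered
#' density modulator, scaled by the ROI amplitudes of `spec` plus a
#' subject-specific deviation, (ii) a multivoxel low-vs-high density pattern
#' (fixed across subjects) driven by the HRF-convolved binary label series,
#' (iii) AR(1) noise, (iv) cosine drift at the high-pass band edge and (v) a
#' partial leak of the motion and respiration nuisance series.
#'
#' @param geom Result of [make_grid_and_rois()].
#' @param events Event table covering the run(s).
#' @param spec An [effect_spec()].
#' @param scale The density scale used for the events.
#' @param pattern_maps Named list of per-ROI pattern vectors (from
#'   [generate_cohort()]); `NULL` draws a fresh pattern.
#' @param subject_dev Numeric deviation added to all of this subject's
#'   univariate amplitudes (default 0).
#' @param pattern_dev Relative deviation of this subject's multivoxel pattern
#'   amplitude: the planted amplitude is scaled by `1 + pattern_dev`
#'   (default 0). Between-subject amplitude variability keeps group
#'   t-statistics finite and realistic.
#' @param n_volumes Number of volumes; default covers the events plus 16 s.
#' @param seed Optional seed.
#' @return Object of class `subject_dataset`: list with `bold` (4D array),
#'   `events`, `nuisance`, `geom`, `n_volumes`, `seed`.
#' @export
generate_subject <- function(geom, events, spec, scale, pattern_maps = NULL,
                             subject_dev = 0, pattern_dev = 0,
                             n_volumes = NULL, seed = NULL) {
  stopifnot(inherits(spec, "effect_spec"), inherits(scale, "density_scale"))
  tr <- geom$grid$tr_s
  n_volumes <- n_volumes %||%
    as.integer(ceiling((max(events$onset + events$duration) + 16) / tr))
  vox <- which(geom$brain)
  v <- length(vox)
  with_seed(seed, {
    nuis <- make_nuisance(n_volumes, tr)
    Y <- ar1_noise(n_volumes, v, spec$ar1, spec$noise_sd)
    # low-frequency drift near the high-pass band edge
    t01 <- (seq_len(n_volumes) - 0.5) / n_volumes
    drift <- spec$drift_amplitude *
      (cos(pi * t01) + 0.5 * cos(2 * pi * t01))
    Y <- Y + drift %o% stats::runif(v, 0.5, 1.5)
    Y <- Y + spec$nuisance_leak *
      (scale(nuis) %*% matrix(stats::rnorm(ncol(nuis) * v, 0, 0.2),
                              ncol(nuis), v))
    # univariate effects
    regs <- list()
    ep <- condition_epochs(events)
    for (cc in unique(ep$condition)) {
      e <- ep[ep$condition == cc, ]
      regs[[cc]] <- hrf_regressor(e$onset, e$duration, rep(1, nrow(e)),
                                  n_volumes, tr)
    }
    dm <- density_modulator(events, scale)
    regs[["density"]] <- hrf_regressor(dm$onset, dm$duration,
                                       dm$value - mean(dm$value),
                                       n_volumes, tr)
    roi_cols <- lapply(geom$rois, function(m) match(which(m), vox))
    for (roi in names(spec$univariate_betas)) {
      amps <- spec$univariate_betas[[roi]]
      cols <- roi_cols[[roi]]
      for (rg in names(amps)) {
        a <- amps[[rg]] + subject_dev
        if (!is.null(regs[[rg]]) && a != 0) {
          Y[, cols] <- Y[, cols] + regs[[rg]] %o% rep(a, length(cols))
        }
      }
    }
    # shared multivoxel density pattern
    if (length(spec$pattern_amplitude)) {
      lab_reg <- label_regressor(events, scale, n_volumes, tr)
      for (roi in names(spec$pattern_amplitude)) {
        a <- spec$pattern_amplitude[[roi]] * (1 + pattern_dev)
        if (a == 0) next
        cols <- roi_cols[[roi]]
        pat <- pattern_maps[[roi]] %||% stats::rnorm(length(cols))
        psd <- spec$pattern_subject_sigma %||% 0
        if (psd > 0) {
          pat <- pat + stats::rnorm(length(cols), 0, psd * stats::sd(pat))
        }
        Y[, cols] <- Y[, cols] + a * (lab_reg %o% pat)
      }
    }
    bold <- array(0, c(geom$grid$shape, n_volumes))
    flat <- matrix(bold, prod(geom$grid$shape), n_volumes)
    flat[vox, ] <- t(Y)
    bold <- array(flat, c(geom$grid$shape, n_volumes))
    structure(list(bold = bold, events = events, nuisance = nuis,
                   geom = geom, n_volumes = n_volumes, seed = seed),
              class = "subject_dataset")
  })
}

#' Generate a multi-subject synthetic cohort
#'
#' The multivoxel density patterns are drawn once and shared across subjects
#' (across-participant decoding requires a consistent voxel-level code);
#' univariate amplitudes receive independent per-subject Gaussian deviations
#' with SD `subject_sigma`, and noise is independent per subject.
#'
#' @param n_subjects Cohort size (default 25).
#' @param geom Result of [make_grid_and_rois()].
#' @param events Event table shared across subjects, or a list of per-subject
#'   event tables.
#' @param spec An [effect_spec()].
#' @param scale The density scale.
#' @param n_volumes Volumes per subject (default from events).
#' @param seed Optional seed.
#' @return List of `subject_dataset` objects with attribute `pattern_maps`.
#' @export
generate_cohort <- function(n_subjects = 25L, geom, events, spec, scale,
                            n_volumes = NULL, seed = NULL) {
  if (n_subjects < 2L) stop("need >= 2 subjects", call. = FALSE)
  with_seed(seed, {
    vox <- which(geom$brain)
    pattern_maps <- lapply(geom$rois, function(m) {
      p <- stats::rnorm(sum(m))
      p - mean(p)
    })
    subjects <- lapply(seq_len(n_subjects), function(s) {
      ev <- if (is.data.frame(events)) events else events[[s]]
      dev <- stats::rnorm(1, 0, spec$subject_sigma)
      pdev <- stats::rnorm(1, 0, spec$pattern_sigma %||% 0.1)
      generate_subject(geom, ev, spec, scale, pattern_maps = pattern_maps,
                       subject_dev = dev, pattern_dev = pdev,
                       n_volumes = n_volumes)
    })
    attr(subjects, "pattern_maps") <- pattern_maps
    subjects
  })
}

#' Extract the in-mask time-by-voxel data matrix
#'
#' @param dataset A `subject_dataset` (or a 4D array).
#' @param mask Logical 3D mask; defaults to the dataset's brain mask.
#' @return Matrix with `n_volumes` rows and one column per in-mask voxel (in
#'   `which(mask)` order).
#' @export
bold_matrix <- function(dataset, mask = NULL) {
  if (inherits(dataset, "subject_dataset")) {
    mask <- mask %||% dataset$geom$brain
    bold <- dataset$bold
  } else {
    bold <- dataset
    if (is.null(mask)) stop("mask required for a bare array", call. = FALSE)
  }
  dm <- dim(bold)
  flat <- matrix(bold, prod(dm[1:3]), dm[4])
  t(flat[which(mask), , drop = FALSE])
}

#' Write a subject dataset to disk (NIfTI + TSV)
#'
#' The 4D BOLD series and brain mask are written as NIfTI-1 files, the events
#' and nuisance series as tab-separated tables, and a JSON sidecar records the
#' grid geometry.
#'
#' @param dataset A `subject_dataset`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default "sub-01").
#' @return The directory, invisibly.
#' @export
write_subject_dataset <- function(dataset, dir, prefix = "sub-01") {
  stopifnot(inherits(dataset, "subject_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- dataset$geom$grid$voxel_size_mm
  img <- RNifti::asNifti(dataset$bold,
                         pixdim = c(vs, vs, vs, dataset$geom$grid$tr_s))
  RNifti::writeNifti(img, file.path(dir, paste0(prefix, "_bold.nii.gz")))
  RNifti::writeNifti(RNifti::asNifti(dataset$geom$brain + 0),
                     file.path(dir, paste0(prefix, "_mask.nii.gz")))
  write_events(dataset$events, file.path(dir, paste0(prefix, "_events.tsv")))
  utils::write.table(dataset$nuisance,
                     file.path(dir, paste0(prefix, "_nuisance.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(shape = dataset$geom$grid$shape, voxel_size_mm = vs,
         tr_s = dataset$geom$grid$tr_s, n_volumes = dataset$n_volumes),
    file.path(dir, paste0(prefix, "_grid.json")), auto_unbox = TRUE)
  invisible(dir)
}
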
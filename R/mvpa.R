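#' Binary labels for multivariate analyses
#'
#' Produces the (onset, duration, label) frame for one of the three label
#' schemes: `"density"` splits the density levels into a lower and an upper
#' half and labels every adjustment-phase stack (labels can therefore change
#' within a trial); `"direction"` labels each adjustment stack by the current
#' adjustment direction (density increasing vs decreasing; unchanged stacks
#' are unlabeled and excluded) and requires adjustment (A) trials only;
#' `"target"` labels whole trials by lower- versus higher-density target and
#' requires memory (M) trials only.
#'
#' @param events Event table (filter to the trials the scheme applies to).
#' @param scheme `"density"`, `"direction"` or `"target"`.
#' @param scale The density scale.
#' @return Data frame with columns `onset`, `duration`, `label`
#'   (`"low"`/`"high"` for density and target, `"down"`/`"up"` for
#'   direction).
#' @export
label_events <- function(events, scheme = c("density", "direction", "target"),
                         scale) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(scale, "density_scale"))
  if (scheme == "density") {
    ev <- events[events$event_type == "adjust_stack" &
                   !is.na(events$density_level), ]
    return(data.frame(onset = ev$onset, duration = ev$duration,
                      label = density_split(scale, ev$density_level),
                      stringsAsFactors = FALSE))
  }
  if (scheme == "direction") {
    if (any(!unique(events$condition) %in% c("MA", "NA"))) {
      stop("direction scheme requires adjustment (MA/NA) trials only",
           call. = FALSE)
    }
    ev <- events[events$event_type == "adjust_stack" &
                   !is.na(events$density_level), ]
    out <- do.call(rbind, lapply(split(ev, ev$trial), function(e) {
      e <- e[order(e$onset), ]
      chg <- c(diff(e$density_level), 0)
      keep <- chg != 0
      data.frame(onset = e$onset[keep], duration = e$duration[keep],
                 label = ifelse(chg[keep] > 0, "up", "down"),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    return(out)
  }
  # target scheme: one label per trial over the whole trial epoch
  if (any(!unique(events$condition) %in% c("MA", "MP"))) {
    stop("target scheme requires memory (MA/MP) trials only", call. = FALSE)
  }
  if (is.null(events$target_level)) {
    stop("target scheme requires a target_level column", call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(events, events$trial), function(e) {
    tl <- e$target_level[1]
    if (is.na(tl)) stop("target scheme requires a target level", call. = FALSE)
    data.frame(onset = min(e$onset),
               duration = max(e$onset + e$duration) - min(e$onset),
               label = density_split(scale, tl), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fit the two-label GLM of a multivariate analysis
#'
#' Builds a design with one HRF-convolved regressor per binary label plus the
#' usual intercept, high-pass basis and nuisance columns, and fits it to a
#' subject's data.
#'
#' @param dataset A `subject_dataset`.
#' @param labels A [label_events()] frame.
#' @param mask Analysis mask (default the subject's brain mask).
#' @param hp_cutoff_hz High-pass cutoff (default 1/230).
#' @param ar1 AR(1) prewhitening (default TRUE).
#' @return List with `betas` (2 x voxels, rows named by label), `residuals`,
#'   `df`.
#' @export
fit_label_glm <- function(dataset, labels, mask = NULL,
                          hp_cutoff_hz = 1 / 230, ar1 = TRUE) {
  stopifnot(inherits(dataset, "subject_dataset"))
  mask <- mask %||% dataset$geom$brain
  tr <- dataset$geom$grid$tr_s
  n_vol <- dataset$n_volumes
  labs <- sort(unique(labels$label))
  if (length(labs) != 2L) stop("need exactly two labels", call. = FALSE)
  Xl <- sapply(labs, function(l) {
    e <- labels[labels$label == l, ]
    hrf_regressor(e$onset, e$duration, rep(1, nrow(e)), n_vol, tr)
  })
  Xh <- dct_highpass_basis(n_vol, tr, hp_cutoff_hz %||% 0)
  X <- cbind(intercept = 1, Xl, Xh, as.matrix(dataset$nuisance))
  Y <- bold_matrix(dataset, mask)
  design <- structure(list(X = X, names = colnames(X), condition_cols = labs,
                           modulator_cols = character(0),
                           n_volumes = n_vol, tr_s = tr),
                      class = "design_matrix")
  fit <- fit_glm(Y, design, ar1 = ar1)
  list(betas = fit$betas[labs, , drop = FALSE], residuals = fit$residuals,
       df = fit$df)
}

#' Spherical searchlight neighborhoods
#'
#' For every in-mask voxel, the set of in-mask voxels whose center-to-center
#' Euclidean distance is at most `radius_mm`. With 3-mm voxels and the 4-mm
#' default radius an interior neighborhood has 7 members (the center and its
#' six face neighbors; edge neighbors lie at 4.24 mm).
#'
#' @param mask Logical 3D array.
#' @param voxel_size_mm Isotropic voxel size.
#' @param radius_mm Searchlight radius (default 4).
#' @return Object of class `searchlight`: list with `centers` (linear voxel
#'   indices), `members` (list of integer vectors of linear indices),
#'   `offsets` (matrix of integer offsets), `mask`.
#' @export
searchlight_neighborhoods <- function(mask, voxel_size_mm = 3, radius_mm = 4) {
  if (radius_mm < 0) stop("radius must be >= 0", call. = FALSE)
  dm <- dim(mask)
  r_vox <- floor(radius_mm / voxel_size_mm)
  off <- expand.grid(dx = -r_vox:r_vox, dy = -r_vox:r_vox, dz = -r_vox:r_vox)
  keep <- voxel_size_mm * sqrt(off$dx^2 + off$dy^2 + off$dz^2) <= radius_mm
  off <- as.matrix(off[keep, , drop = FALSE])
  centers <- which(mask)
  ijk <- arrayInd(centers, dm)
  members <- lapply(seq_along(centers), function(i) {
    nb <- sweep(off, 2, ijk[i, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- (nb[, 3] - 1) * dm[1] * dm[2] + (nb[, 2] - 1) * dm[1] + nb[, 1]
    lin[mask[lin]]
  })
  pos <- integer(prod(dm))
  pos[centers] <- seq_along(centers)
  member_pos <- lapply(members, function(m) pos[m])
  structure(list(centers = centers, members = members,
                 member_pos = member_pos, offsets = off, mask = mask),
            class = "searchlight")
}

# Ledoit-Wolf shrinkage intensity for off-diagonal shrinkage toward zero,
# computed on standardized residuals (i.e. correlations shrunk toward the
# identity) so the intensity is invariant to voxelwise rescaling
lw_shrinkage <- function(res) {
  n <- nrow(res)
  xc <- sweep(res, 2, colMeans(res))
  sds <- sqrt(colSums(xc^2) / n)
  sds[sds == 0] <- 1
  z <- sweep(xc, 2, sds, "/")
  R <- crossprod(z) / n
  V <- (crossprod(z^2) / n - R^2) / n   # var of each correlation entry
  off <- row(R) != col(R)
  num <- sum(V[off])
  den <- sum(R[off]^2)
  if (den <= 0) return(1)
  max(0, min(1, num / den))
}

#' Whiten betas with Ledoit-Wolf variance-retaining noise normalization
#'
#' Estimates the noise covariance of the member voxels from the GLM residuals
#' with Ledoit-Wolf shrinkage toward the diagonal of the sample covariance
#' (variances are retained, off-diagonal covariances shrunk), then transforms
#' the beta patterns by the inverse matrix square root of the regularized
#' covariance.
#'
#' @param betas Conditions-by-voxels matrix (e.g. the two label betas over one
#'   neighborhood).
#' @param residuals Time-by-voxels residual matrix from the same GLM.
#' @param lambda Shrinkage weight in \[0, 1\]; `NULL` (default) uses the
#'   Ledoit-Wolf estimate. 1 reduces to per-voxel scaling by residual SD.
#' @return Whitened betas (same shape). The attribute `"whitener"` carries the
#'   transform matrix.
#' @export
whiten_betas <- function(betas, residuals, lambda = NULL) {
  P <- ncol(betas)
  if (ncol(residuals) != P) stop("betas/residual voxel mismatch", call. = FALSE)
  if (nrow(residuals) <= P) {
    stop("neighborhood larger than residual degrees of freedom", call. = FALSE)
  }
  lambda <- lambda %||% lw_shrinkage(residuals)
  xc <- sweep(residuals, 2, colMeans(residuals))
  S <- crossprod(xc) / nrow(residuals)
  Sigma <- (1 - lambda) * S + lambda * diag(diag(S), P)
  eg <- eigen(Sigma, symmetric = TRUE)
  vals <- pmax(eg$values, 1e-10)
  W <- eg$vectors %*% (t(eg$vectors) / sqrt(vals))
  out <- betas %*% W
  attr(out, "whitener") <- W
  out
}

#' Leave-one-participant-out crossnobis searchlight
#'
#' For each searchlight neighborhood and each cross-validation fold (one fold
#' per left-out subject), computes the cross-validated whitened Euclidean
#' ("crossnobis") distance between the two label patterns:
#' `d = (mean of training subjects' whitened pattern difference) . (left-out
#' subject's whitened pattern difference) / P`, with P the neighborhood size.
#' The estimator is unbiased: it averages to zero when no consistent pattern
#' distinguishes the labels, and can be negative on individual folds.
#'
#' @param subject_fits List (one per subject) of [fit_label_glm()] results on
#'   a common mask.
#' @param sl A [searchlight_neighborhoods()] object on the same mask.
#' @param whiten Apply per-neighborhood Ledoit-Wolf whitening using each
#'   subject's residuals (default TRUE). With `FALSE` the distances are
#'   cross-validated Euclidean.
#' @param cross_validate `TRUE` (default) for the unbiased leave-one-out
#'   estimator; `FALSE` computes each fold's naive squared distance
#'   `||delta_f||^2 / P`, which is positively biased under the null (exposed
#'   for calibration contrasts).
#' @return List of 3D fold distance maps (`NA` outside the mask), one per
#'   subject, in subject order.
#' @export
crossnobis_loso <- function(subject_fits, sl, whiten = TRUE,
                            cross_validate = TRUE) {
  S <- length(subject_fits)
  if (S < 3L) stop("need >= 3 subjects", call. = FALSE)
  V <- length(sl$centers)
  for (f in subject_fits) {
    if (ncol(f$betas) != V) stop("subject betas do not match the mask", call. = FALSE)
    if (nrow(f$betas) != 2L) stop("two labels required per subject", call. = FALSE)
  }
  # per-subject raw pattern differences over in-mask voxels
  D <- t(vapply(subject_fits, function(f) f$betas[1, ] - f$betas[2, ],
                numeric(V)))
  member_pos <- sl$member_pos %||%
    lapply(sl$members, function(m) match(m, sl$centers))
  dists <- matrix(NA_real_, S, V)
  if (!whiten) {
    for (f in seq_len(S)) {
      train <- if (cross_validate) colMeans(D[-f, , drop = FALSE]) else D[f, ]
      prod_map <- train * D[f, ]
      dists[f, ] <- vapply(member_pos, function(m) mean(prod_map[m]),
                           numeric(1))
    }
  } else {
    for (c in seq_len(V)) {
      m <- member_pos[[c]]
      P <- length(m)
      Dw <- t(vapply(seq_len(S), function(s) {
        as.numeric(whiten_betas(D[s, m, drop = FALSE],
                                subject_fits[[s]]$residuals[, m, drop = FALSE]))
      }, numeric(P)))
      for (f in seq_len(S)) {
        train <- if (cross_validate) colMeans(Dw[-f, , drop = FALSE]) else Dw[f, ]
        dists[f, c] <- sum(train * Dw[f, ]) / P
      }
    }
  }
  lapply(seq_len(S), function(f) {
    out <- array(NA_real_, dim(sl$mask))
    out[sl$centers] <- dists[f, ]
    out
  })
}

#' Gaussian spatial smoothing of a 3D map
#'
#' Separable Gaussian smoothing with the stated full-width at half-maximum
#' (`sigma = fwhm / (2 sqrt(2 log 2))`). `NA` voxels (outside the mask) are
#' excluded and the kernel renormalized over available voxels, so values are
#' not dragged toward zero at mask edges. `fwhm_mm = 0` returns the input.
#'
#' @param vol 3D array (may contain `NA`).
#' @param fwhm_mm Kernel FWHM in mm.
#' @param voxel_size_mm Isotropic voxel size.
#' @return Smoothed array with `NA` where the input was `NA`.
#' @export
smooth_volume <- function(vol, fwhm_mm, voxel_size_mm = 3) {
  if (fwhm_mm == 0) return(vol)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  na_mask <- is.na(vol)
  x <- vol; x[na_mask] <- 0
  w <- array(as.numeric(!na_mask), dim(vol))
  conv1 <- function(a, along) {
    dm <- dim(a)
    perm <- switch(along, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(a, perm)
    n <- dim(ap)[1]
    m <- matrix(ap, n)
    padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[(j - 1) + seq_len(n), , drop = FALSE]
    }
    aperm(array(out, dim(ap)), order(perm))
  }
  for (d in 1:3) {
    x <- conv1(x, d)
    w <- conv1(w, d)
  }
  out <- x / w
  out[na_mask] <- NA_real_
  out
}

#' Smooth fold distance maps and run group inference
#'
#' Smooths each fold's distance image with a Gaussian kernel (default 6-mm
#' FWHM), then tests the fold maps against zero with a one-sample t-test and
#' the sign-flip permutation FWE procedure shared with the univariate
#' pipeline. Distances are tested one-sided (information present means
#' positive distance).
#'
#' @param fold_maps List of 3D fold distance maps from [crossnobis_loso()].
#' @param mask Analysis mask.
#' @param fwhm_mm Smoothing kernel FWHM (default 6).
#' @param voxel_size_mm Voxel size (default 3).
#' @param alpha FWE level (default 0.05).
#' @param min_cluster Minimum cluster extent (default 5).
#' @param svc_mask Optional small-volume mask.
#' @param seed Optional seed for Monte-Carlo permutations.
#' @return A [threshold_fwe()] result.
#' @export
smooth_and_test <- function(fold_maps, mask, fwhm_mm = 6, voxel_size_mm = 3,
                            alpha = 0.05, min_cluster = 5L, svc_mask = NULL,
                            seed = NULL) {
  if (length(fold_maps) < 3L) stop("need >= 3 fold maps", call. = FALSE)
  sm <- lapply(fold_maps, smooth_volume, fwhm_mm = fwhm_mm,
               voxel_size_mm = voxel_size_mm)
  vox <- which(mask)
  maps <- t(vapply(sm, function(v) v[vox], numeric(length(vox))))
  threshold_fwe(maps, mask, alpha = alpha, method = "permutation",
                min_cluster = min_cluster, svc_mask = svc_mask,
                alternative = "greater", seed = seed)
}
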
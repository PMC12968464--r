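#' Canonical double-gamma haemodynamic response function
#'
#' The canonical HRF is the difference of two gamma densities: a response
#' peaking at 6 s and an undershoot peaking at 16 s with peak/undershoot
#' ratio 6, evaluated over 32 s and normalized to unit peak.
#'
#' @param dt_s Sampling interval of the kernel in seconds.
#' @param duration_s Kernel length (default 32).
#' @param peak_s,undershoot_s Gamma peak delays (defaults 6 and 16).
#' @param ratio Peak-to-undershoot amplitude ratio (default 6).
#' @return Numeric kernel sampled at `dt_s`, starting at t = 0.
#' @export
canonical_hrf <- function(dt_s, duration_s = 32, peak_s = 6, undershoot_s = 16,
                          ratio = 6) {
  if (dt_s <= 0) stop("dt_s must be > 0", call. = FALSE)
  t <- seq(0, duration_s, by = dt_s)
  # gamma densities with unit scale parameterized by peak delay (shape = peak + 1)
  h <- stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    stats::dgamma(t, shape = undershoot_s + 1, rate = 1) / ratio
  h / max(h)
}

# Convolve (onset, duration, amplitude) events with the canonical HRF and
# sample at the volume acquisition times.
hrf_regressor <- function(onsets, durations, amplitudes, n_volumes, tr_s,
                          oversample = 8L) {
  dt <- tr_s / oversample
  total <- n_volumes * tr_s
  n_hi <- ceiling(total / dt) + 1L
  stim <- numeric(n_hi)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1L
    b <- max(a, ceiling((onsets[i] + durations[i]) / dt))
    if (a > n_hi) next
    b <- min(b, n_hi)
    stim[a:b] <- stim[a:b] + amplitudes[i]
  }
  h <- canonical_hrf(dt)
  conv <- stats::convolve(stim, rev(h), type = "open")[seq_len(n_hi)] * dt
  frame_idx <- floor((seq_len(n_volumes) - 1L) * tr_s / dt) + 1L
  conv[frame_idx]
}

#' Discrete cosine high-pass basis
#'
#' Cosine regressors spanning frequencies below the high-pass cutoff,
#' `K = floor(2 * T * cutoff_hz)` columns for a run of duration `T` seconds.
#'
#' @param n_volumes Number of volumes.
#' @param tr_s Volume acquisition time (s).
#' @param cutoff_hz High-pass cutoff (default 1/230 Hz).
#' @return Matrix with `n_volumes` rows and `K` columns (may have 0 columns).
#' @export
dct_highpass_basis <- function(n_volumes, tr_s, cutoff_hz = 1 / 230) {
  T_s <- n_volumes * tr_s
  K <- floor(2 * T_s * cutoff_hz)
  if (K < 1) return(matrix(0, n_volumes, 0))
  t <- seq_len(n_volumes) - 0.5
  X <- sapply(seq_len(K), function(k) cos(pi * k * t / n_volumes))
  matrix(X, nrow = n_volumes,
         dimnames = list(NULL, paste0("hp_cos", seq_len(K))))
}

condition_epochs <- function(events) {
  # whole-trial epochs per condition: trial onset to end of its last event
  split_ev <- split(events, events$trial)
  do.call(rbind, lapply(split_ev, function(e) {
    data.frame(condition = e$condition[1],
               onset = min(e$onset),
               duration = max(e$onset + e$duration) - min(e$onset))
  }))
}

#' Parametric modulator event frames
#'
#' Helpers building (onset, duration, value) frames for the standard
#' modulators: the log density of every adjustment-phase stack
#' (`density_modulator`, all conditions), elapsed time within the adjustment
#' phase (`time_modulator`) and absolute distance from target in levels
#' (`distance_modulator`), both over MA trials by default.
#'
#' @param events An event table from [as_event_table()].
#' @param scale The density scale (for log tone counts).
#' @param conditions Conditions whose stacks enter the modulator.
#' @return Data frame with columns `onset`, `duration`, `value`.
#' @export
density_modulator <- function(events, scale,
                              conditions = c("MA", "MP", "NA", "NP")) {
  ev <- events[events$event_type == "adjust_stack" &
                 events$condition %in% conditions &
                 !is.na(events$density_level), ]
  data.frame(onset = ev$onset, duration = ev$duration,
             value = log(scale$levels[ev$density_level]))
}

#' @rdname density_modulator
#' @export
time_modulator <- function(events, conditions = "MA") {
  ev <- events[events$event_type == "adjust_stack" &
                 events$condition %in% conditions, ]
  val <- stats::ave(ev$onset, ev$trial, FUN = function(x) x - min(x))
  data.frame(onset = ev$onset, duration = ev$duration, value = val)
}

#' @rdname density_modulator
#' @param target_levels Named vector of target level per trial id.
#' @export
distance_modulator <- function(events, target_levels, conditions = "MA") {
  ev <- events[events$event_type == "adjust_stack" &
                 events$condition %in% conditions &
                 !is.na(events$density_level), ]
  data.frame(onset = ev$onset, duration = ev$duration,
             value = abs(ev$density_level -
                           target_levels[as.character(ev$trial)]))
}

#' Assemble a first-level design matrix
#'
#' Builds HRF-convolved boxcar regressors for each condition's whole-trial
#' epoch, centered parametric modulators serially orthogonalized (each against
#' the condition boxcars and all earlier modulators, in the declared order), a
#' cosine high-pass basis below `hp_cutoff_hz`, nuisance columns and an
#' intercept. Modulators that are constant over their events reduce to zero
#' columns after centering and are dropped with a warning.
#'
#' @param events Event table from [as_event_table()].
#' @param n_volumes,tr_s Scan geometry.
#' @param modulators Named list of modulator frames (see
#'   [density_modulator()]).
#' @param nuisance Optional matrix of nuisance series (`n_volumes` rows).
#' @param hp_cutoff_hz High-pass cutoff (default 1/230 Hz; `NULL` to omit).
#' @param oversample Temporal oversampling for convolution (default 8).
#' @return Object of class `design_matrix`: list with `X`, `names`,
#'   `condition_cols`, `modulator_cols`, `n_volumes`, `tr_s`.
#' @export
build_design <- function(events, n_volumes, tr_s, modulators = NULL,
                         nuisance = NULL, hp_cutoff_hz = 1 / 230,
                         oversample = 8L) {
  stopifnot(n_volumes > 0, tr_s > 0)
  if (max(events$onset + events$duration) > n_volumes * tr_s) {
    stop("events extend beyond the scan duration", call. = FALSE)
  }
  ep <- condition_epochs(events)
  conds <- sort(unique(ep$condition))
  Xc <- sapply(conds, function(cc) {
    e <- ep[ep$condition == cc, ]
    hrf_regressor(e$onset, e$duration, rep(1, nrow(e)), n_volumes, tr_s,
                  oversample)
  })
  colnames(Xc) <- conds
  Xm <- NULL
  if (length(modulators)) {
    if (is.null(names(modulators)) || any(names(modulators) == "")) {
      stop("modulators must be a named list", call. = FALSE)
    }
    keep <- list()
    for (nm in names(modulators)) {
      mo <- modulators[[nm]]
      v <- mo$value - mean(mo$value)     # center over the modulator's support
      if (all(abs(v) < 1e-12)) {
        warning(sprintf("modulator '%s' is constant after centering; dropped", nm))
        next
      }
      reg <- hrf_regressor(mo$onset, mo$duration, v, n_volumes, tr_s,
                           oversample)
      # serial orthogonalization: condition boxcars, then earlier modulators
      basis <- cbind(1, Xc, if (length(keep)) do.call(cbind, keep))
      reg <- stats::lsfit(basis, reg, intercept = FALSE)$residuals
      keep[[nm]] <- reg
    }
    if (length(keep)) {
      Xm <- do.call(cbind, keep)
      colnames(Xm) <- names(keep)
    }
  }
  Xh <- if (is.null(hp_cutoff_hz)) matrix(0, n_volumes, 0) else
    dct_highpass_basis(n_volumes, tr_s, hp_cutoff_hz)
  Xn <- NULL
  if (!is.null(nuisance)) {
    Xn <- as.matrix(nuisance)
    if (nrow(Xn) != n_volumes) stop("nuisance rows != n_volumes", call. = FALSE)
    if (is.null(colnames(Xn))) colnames(Xn) <- paste0("nuis", seq_len(ncol(Xn)))
  }
  X <- cbind(intercept = 1, Xc, Xm, Xh, Xn)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(X = X, names = colnames(X), condition_cols = conds,
                 modulator_cols = colnames(Xm) %||% character(0),
                 n_volumes = n_volumes, tr_s = tr_s),
            class = "design_matrix")
}

#' Fit a voxelwise GLM
#'
#' Ordinary least squares per voxel, optionally with AR(1) prewhitening: the
#' lag-1 autocorrelation of the OLS residuals is pooled over in-mask voxels
#' and both data and design are filtered by the corresponding whitening
#' transform before refitting.
#'
#' @param Y Numeric matrix, `n_volumes` rows by voxels columns (see
#'   [bold_matrix()]).
#' @param design A [build_design()] object.
#' @param ar1 Apply AR(1) prewhitening (default `TRUE`).
#' @return Object of class `glm_fit`: `betas` (columns = voxels), `residuals`,
#'   `sigma2`, `df`, `rho`, `design`.
#' @export
fit_glm <- function(Y, design, ar1 = TRUE) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X
  if (nrow(Y) != nrow(X)) stop("Y rows must equal design rows", call. = FALSE)
  ols <- function(X, Y) {
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) stop("singular design", call. = FALSE)
    B <- qr.coef(qrx, Y)
    R <- Y - X %*% B
    list(B = B, R = R)
  }
  f <- ols(X, Y)
  rho <- 0
  if (ar1) {
    n <- nrow(Y)
    num <- sum(f$R[-1, , drop = FALSE] * f$R[-n, , drop = FALSE])
    den <- sum(f$R^2)
    rho <- if (den > 0) num / den else 0
    if (abs(rho) > 1e-3) {
      W <- function(M) {
        M2 <- M
        M2[1, ] <- M[1, ] * sqrt(1 - rho^2)
        M2[-1, ] <- M[-1, , drop = FALSE] - rho * M[-n, , drop = FALSE]
        M2
      }
      f <- ols(W(X), W(Y))
    }
  }
  df <- nrow(Y) - ncol(X)
  sigma2 <- colSums(f$R^2) / df
  structure(list(betas = f$B, residuals = f$R, sigma2 = sigma2, df = df,
                 rho = rho, design = design),
            class = "glm_fit")
}

#' Linear contrast of condition betas
#'
#' @param fit A [fit_glm()] result.
#' @param weights Named numeric vector over design columns (e.g.
#'   `c(MA = 1, MP = 1, NA = -1, NP = -1)` for the memory main effect,
#'   `c(MA = 1, NA = 1, MP = -1, NP = -1)` for adjustment, and
#'   `c(MA = 1, MP = -1, NA = -1, NP = 1)` for their interaction).
#' @return Numeric vector of contrast values per voxel. A warning is raised
#'   for multi-column difference contrasts whose weights do not sum to zero.
#' @export
contrast_map <- function(fit, weights) {
  stopifnot(inherits(fit, "glm_fit"))
  if (is.null(names(weights)) ||
      !all(names(weights) %in% rownames(fit$betas))) {
    stop("weights must be named after design columns", call. = FALSE)
  }
  if (length(weights) > 1 && any(weights < 0) &&
      abs(sum(weights)) > 1e-12) {
    warning("difference contrast weights do not sum to zero")
  }
  drop(crossprod(fit$betas[names(weights), , drop = FALSE], weights))
}

#' Group-level one-sample t map
#'
#' Voxelwise one-sample t-test of subject contrast values against zero,
#' `df = n - 1`. Voxels with zero between-subject variance (including
#' identical nonzero maps, where t would be infinite) are returned as `NA`.
#'
#' @param maps Matrix, subjects in rows, voxels in columns.
#' @return List with `t` (per voxel), `df`, `mean`.
#' @export
group_inference <- function(maps) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n < 3L) stop("need >= 3 subjects", call. = FALSE)
  m <- colMeans(maps)
  s <- sqrt(colSums(sweep(maps, 2, m)^2) / (n - 1))
  t <- ifelse(s > 0, m / (s / sqrt(n)), NA_real_)
  list(t = t, df = n - 1L, mean = m)
}

#' Label 6-connected clusters in a 3D logical volume
#'
#' @param mask Logical 3D array.
#' @return Integer array of the same shape; 0 outside clusters.
#' @export
label_clusters <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nb_off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  coords <- arrayInd(idx, dm)
  key <- function(ijk) (ijk[, 3] - 1) * dm[1] * dm[2] + (ijk[, 2] - 1) * dm[1] + ijk[, 1]
  inmask <- logical(prod(dm)); inmask[idx] <- TRUE
  cur <- 0L
  for (v in idx) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    lab[v] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(p, dm)
      for (q in seq_len(6)) {
        nb <- ijk + nb_off[q, , drop = FALSE]
        if (any(nb < 1) || any(nb > dm)) next
        k <- key(nb)
        if (inmask[k] && lab[k] == 0L) {
          lab[k] <- cur
          queue <- c(queue, k)
        }
      }
    }
  }
  lab
}

#' Family-wise-error thresholding of a group map
#'
#' Controls the voxelwise family-wise error over the analysis mask either by
#' sign-flip max-statistic permutation (default; exact enumeration of all
#' 2^n sign patterns when n <= 12, otherwise Monte-Carlo) or by Bonferroni
#' correction. Suprathreshold voxels are grouped into 6-connected clusters
#' and clusters smaller than `min_cluster` discarded. Passing `svc_mask`
#' restricts the whole procedure to an a priori region (small-volume
#' correction).
#'
#' @param maps Subjects-by-voxels matrix of contrast (or distance) values for
#'   in-mask voxels.
#' @param mask Logical 3D array selecting the analysis voxels (columns of
#'   `maps` correspond to `which(mask)`).
#' @param alpha FWE level in (0, 1) (default 0.05).
#' @param method `"permutation"` or `"bonferroni"`.
#' @param min_cluster Minimum cluster extent in voxels (default 5).
#' @param svc_mask Optional logical 3D array (subset of `mask`) for
#'   small-volume correction.
#' @param n_perm Monte-Carlo permutations when exact enumeration is
#'   infeasible (default 2000).
#' @param alternative `"two.sided"` (max |t|), `"greater"` or `"less"`.
#' @param seed Optional seed for Monte-Carlo permutations.
#' @return List with `t_map` (3D, `NA` outside the mask), `threshold`,
#'   `supra` (logical 3D), `clusters` (data frame: cluster, n_voxels, peak_x,
#'   peak_y, peak_z, peak_stat), `fwe_p` (p-value of the most extreme
#'   statistic), `df`.
#' @export
threshold_fwe <- function(maps, mask, alpha = 0.05,
                          method = c("permutation", "bonferroni"),
                          min_cluster = 5L, svc_mask = NULL, n_perm = 2000L,
                          alternative = c("two.sided", "greater", "less"),
                          seed = NULL) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  maps <- as.matrix(maps)
  vox <- which(mask)
  if (ncol(maps) != length(vox)) {
    stop("columns of maps must match in-mask voxels", call. = FALSE)
  }
  use <- rep(TRUE, length(vox))
  if (!is.null(svc_mask)) use <- svc_mask[vox]
  n <- nrow(maps)
  gi <- group_inference(maps)
  stat <- switch(alternative,
                 two.sided = abs(gi$t), greater = gi$t, less = -gi$t)
  M <- maps[, use, drop = FALSE]
  t_of <- function(S) {
    # S: permutations x subjects sign matrix
    mu <- (S %*% M) / n
    ss <- matrix(colSums(M^2), nrow(S), ncol(M), byrow = TRUE)
    sd <- sqrt(pmax(ss / n - mu^2, 0) * n / (n - 1))
    tt <- mu / (sd / sqrt(n))
    tt[!is.finite(tt)] <- 0
    tt
  }
  if (method == "permutation") {
    S <- with_seed(seed, {
      if (n <= 12L) {
        as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      } else {
        rbind(rep(1, n),
              matrix(sample(c(-1, 1), (n_perm - 1L) * n, replace = TRUE),
                     ncol = n))
      }
    })
    Tperm <- t_of(unname(as.matrix(S)))
    if (alternative == "two.sided") Tperm <- abs(Tperm)
    if (alternative == "less") Tperm <- -Tperm
    maxT <- apply(Tperm, 1, max)
    threshold <- stats::quantile(maxT, 1 - alpha, type = 1, names = FALSE)
    obs_max <- suppressWarnings(max(stat[use], na.rm = TRUE))
    fwe_p <- mean(maxT >= obs_max)
  } else {
    m_eff <- sum(use)
    p_bonf <- alpha / m_eff
    q <- if (alternative == "two.sided") 1 - p_bonf / 2 else 1 - p_bonf
    threshold <- stats::qt(q, df = gi$df)
    obs_max <- suppressWarnings(max(stat[use], na.rm = TRUE))
    p1 <- stats::pt(obs_max, df = gi$df, lower.tail = FALSE)
    fwe_p <- min(1, m_eff * (if (alternative == "two.sided") 2 * p1 else p1))
  }
  supra_vec <- !is.na(stat) & stat > threshold & use
  supra <- array(FALSE, dim(mask)); supra[vox[supra_vec]] <- TRUE
  lab <- label_clusters(supra)
  clusters <- data.frame(cluster = integer(0), n_voxels = integer(0),
                         peak_x = integer(0), peak_y = integer(0),
                         peak_z = integer(0), peak_stat = numeric(0))
  if (any(lab > 0)) {
    stat_map3 <- array(NA_real_, dim(mask)); stat_map3[vox] <- stat
    keep_id <- 0L
    for (cid in seq_len(max(lab))) {
      members <- which(lab == cid)
      if (length(members) < min_cluster) {
        supra[members] <- FALSE
        next
      }
      keep_id <- keep_id + 1L
      pk <- members[which.max(stat_map3[members])]
      ijk <- arrayInd(pk, dim(mask))
      clusters <- rbind(clusters, data.frame(
        cluster = keep_id, n_voxels = length(members),
        peak_x = ijk[1], peak_y = ijk[2], peak_z = ijk[3],
        peak_stat = gi$t[match(pk, vox)]))
    }
  }
  t_map <- array(NA_real_, dim(mask)); t_map[vox] <- gi$t
  list(t_map = t_map, threshold = threshold, supra = supra,
       clusters = clusters, fwe_p = fwe_p, df = gi$df)
}
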
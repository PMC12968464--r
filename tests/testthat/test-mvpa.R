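test_that("density labels split levels at the median and can switch in-trial", {
  sc <- test_scale()
  sess <- test_session()
  ev <- sess$events[[1]]
  labs <- label_events(ev, "density", sc)
  adj <- ev[ev$event_type == "adjust_stack", ]
  expect_identical(nrow(labs), nrow(adj))
  expect_identical(labs$label, unname(density_split(sc, adj$density_level)))
  # trials whose series crosses the median switch label within the trial
  crosses <- tapply(adj$density_level, adj$trial,
                    function(x) any(x <= 13) && any(x >= 14))
  per_trial <- tapply(labs$label, adj$trial, function(x) length(unique(x)))
  expect_true(all(per_trial[crosses] == 2))
})

test_that("direction and target schemes enforce their preconditions", {
  sc <- test_scale()
  ev <- test_session()$events[[1]]
  adj_ev <- ev[ev$condition %in% c("MA", "NA"), ]
  dl <- label_events(adj_ev, "direction", sc)
  expect_true(all(dl$label %in% c("up", "down")))
  expect_error(label_events(ev, "direction", sc), "MA/NA")
  mem_ev <- ev[ev$condition %in% c("MA", "MP"), ]
  tl <- label_events(mem_ev, "target", sc)
  expect_identical(nrow(tl), length(unique(mem_ev$trial)))
  expect_error(label_events(ev[ev$condition == "NA", ], "target", sc),
               "memory")
})

test_that("searchlight neighborhoods match the 4-mm sphere geometry", {
  mask <- array(TRUE, c(7, 7, 7))
  sl <- searchlight_neighborhoods(mask, voxel_size_mm = 3, radius_mm = 4)
  # interior voxel: center + 6 face neighbors (edge neighbors at 4.24 mm)
  ctr <- which(sl$centers == (3 * 49 + 3 * 7 + 4))  # voxel (4,4,4)
  expect_length(sl$members[[ctr]], 7)
  # corner voxel clipped to the mask
  expect_length(sl$members[[1]], 4)
  sl0 <- searchlight_neighborhoods(mask, 3, 0)
  expect_true(all(lengths(sl0$members) == 1))
})

test_that("whitening handles the limiting and analytic cases", {
  set.seed(4)
  # white residuals: whitening is close to per-voxel scaling by the SD
  res <- matrix(rnorm(4000 * 5), 4000, 5)
  b <- matrix(rnorm(10), 2, 5)
  wb <- whiten_betas(b, res)
  expect_lt(max(abs(wb - b)), 0.15)
  # full shrinkage: exactly per-voxel scaling
  res2 <- matrix(rnorm(200 * 3, sd = c(1, 2, 4)), 200, 3, byrow = TRUE)
  b2 <- matrix(1, 1, 3)
  wb2 <- whiten_betas(b2, res2, lambda = 1)
  sds <- sqrt(diag(crossprod(sweep(res2, 2, colMeans(res2))) / nrow(res2)))
  expect_equal(as.numeric(wb2), 1 / sds, tolerance = 1e-8)
  # known 2-voxel correlated noise: whitener satisfies W' Sigma W = I
  Sigma <- matrix(c(1, 0.6, 0.6, 1), 2)
  L <- chol(Sigma)
  res3 <- matrix(rnorm(2e5), ncol = 2) %*% L
  wb3 <- whiten_betas(matrix(0, 1, 2), res3, lambda = 0)
  W <- attr(wb3, "whitener")
  expect_equal(t(W) %*% Sigma %*% W, diag(2), tolerance = 0.02)
  # neighborhoods larger than the residual frames are rejected
  expect_error(whiten_betas(matrix(0, 2, 10), matrix(rnorm(50), 5, 10)),
               "degrees of freedom")
})

test_that("crossnobis distances are exact for planted noiseless patterns", {
  mask <- array(TRUE, c(5, 5, 5))
  sl <- searchlight_neighborhoods(mask, 3, 4)
  V <- length(sl$centers)
  delta <- numeric(V)
  roi <- 40:60
  delta[roi] <- 2
  fits <- lapply(1:4, function(s) {
    list(betas = rbind(delta, numeric(V)), residuals = NULL)
  })
  maps <- crossnobis_loso(fits, sl, whiten = FALSE)
  expect_length(maps, 4)
  # d at a center = mean over members of delta^2
  expected <- vapply(sl$members, function(m) {
    mean(delta[match(m, sl$centers)]^2)
  }, numeric(1))
  for (f in 1:4) expect_equal(maps[[f]][sl$centers], expected)
})

test_that("zero test patterns give zero distance", {
  mask <- array(TRUE, c(4, 4, 4))
  sl <- searchlight_neighborhoods(mask, 3, 4)
  V <- length(sl$centers)
  set.seed(11)
  fits <- lapply(1:4, function(s) {
    d <- if (s == 1) numeric(V) else rnorm(V)
    list(betas = rbind(d, numeric(V)), residuals = NULL)
  })
  maps <- crossnobis_loso(fits, sl, whiten = FALSE)
  expect_true(all(abs(maps[[1]][sl$centers]) < 1e-12))
})

test_that("cross-validation removes the bias the naive distance carries", {
  mask <- array(TRUE, c(6, 6, 6))
  sl <- searchlight_neighborhoods(mask, 3, 4)
  V <- length(sl$centers)
  set.seed(12)
  cv_means <- naive_means <- numeric(40)
  for (r in 1:40) {
    fits <- lapply(1:6, function(s) {
      list(betas = rbind(rnorm(V), rnorm(V)), residuals = NULL)
    })
    cv <- crossnobis_loso(fits, sl, whiten = FALSE)
    nv <- crossnobis_loso(fits, sl, whiten = FALSE, cross_validate = FALSE)
    cv_means[r] <- mean(vapply(cv, function(m) mean(m[sl$centers]), numeric(1)))
    naive_means[r] <- mean(vapply(nv, function(m) mean(m[sl$centers]), numeric(1)))
  }
  se <- sd(cv_means) / sqrt(length(cv_means))
  expect_lt(abs(mean(cv_means)), 3 * se)      # unbiased under the null
  expect_gt(mean(naive_means), 10 * se)       # naive estimator biased up
})

test_that("fold structure follows leave-one-subject-out", {
  mask <- array(TRUE, c(4, 4, 3))
  sl <- searchlight_neighborhoods(mask, 3, 4)
  V <- length(sl$centers)
  set.seed(13)
  fits <- lapply(1:5, function(s) list(betas = rbind(rnorm(V), rnorm(V)),
                                       residuals = NULL))
  maps <- crossnobis_loso(fits, sl, whiten = FALSE)
  expect_length(maps, 5)
  # perturbing one subject changes that fold and the training of the others,
  # but fold f's map depends on subject f's pattern as the test side
  fits2 <- fits
  fits2[[2]]$betas <- fits2[[2]]$betas * 0
  maps2 <- crossnobis_loso(fits2, sl, whiten = FALSE)
  expect_true(all(abs(maps2[[2]][sl$centers]) < 1e-12))
})

test_that("distances are invariant to joint voxel rescaling", {
  mask <- array(TRUE, c(4, 4, 3))
  sl <- searchlight_neighborhoods(mask, 3, 4)
  V <- length(sl$centers)
  set.seed(14)
  scale_v <- runif(V, 0.5, 3)
  fits <- lapply(1:4, function(s) {
    list(betas = rbind(rnorm(V), rnorm(V)),
         residuals = matrix(rnorm(300 * V), 300, V))
  })
  fits_scaled <- lapply(fits, function(f) {
    list(betas = sweep(f$betas, 2, scale_v, "*"),
         residuals = sweep(f$residuals, 2, scale_v, "*"))
  })
  m1 <- crossnobis_loso(fits, sl, whiten = TRUE)
  m2 <- crossnobis_loso(fits_scaled, sl, whiten = TRUE)
  # invariance holds up to the per-subject covariance estimation error:
  # each subject's own whitener absorbs the rescaling of its voxels
  for (f in 1:4) {
    expect_equal(m1[[f]][sl$centers], m2[[f]][sl$centers], tolerance = 0.05)
  }
})

test_that("gaussian smoothing has the requested FWHM profile", {
  vol <- array(0, c(15, 15, 15))
  vol[8, 8, 8] <- 1
  expect_identical(smooth_volume(vol, 0), vol)
  sm <- smooth_volume(vol, fwhm_mm = 6, voxel_size_mm = 3)
  sigma_vox <- 6 / (2 * sqrt(2 * log(2))) / 3
  profile <- sm[8:12, 8, 8] / sm[8, 8, 8]
  expect_equal(profile, exp(-(0:4)^2 / (2 * sigma_vox^2)), tolerance = 0.02)
  # half maximum reached at FWHM/2 = 1 voxel from the peak
  expect_equal(sm[9, 8, 8] / sm[8, 8, 8], 0.5, tolerance = 0.02)
})
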
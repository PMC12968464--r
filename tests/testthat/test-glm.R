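test_that("canonical HRF has the double-gamma shape", {
  h <- canonical_hrf(0.1)
  t <- seq(0, 32, by = 0.1)
  expect_equal(h[1], 0)                       # zero at onset
  expect_equal(max(h), 1)                     # unit peak normalization
  peak_t <- t[which.max(h)]
  expect_gt(peak_t, 3); expect_lt(peak_t, 7)  # peak near 5 s
  expect_gt(sum(h), 0)                        # net positive response
  expect_lt(min(h), 0)                        # undershoot present
})

test_that("cosine high-pass basis has floor(2 T fc) columns", {
  # 510-s run at 1/230 Hz: floor(2 * 510 / 230) = 4 columns
  X <- dct_highpass_basis(510, 1, 1 / 230)
  expect_identical(ncol(X), 4L)
  expect_identical(ncol(dct_highpass_basis(100, 1, 1 / 1000)), 0L)
})

test_that("modulators are centered and serially orthogonalized", {
  sc <- test_scale()
  ev <- test_session()$events[[1]]
  ev <- ev[ev$event_type != "press", ]
  n_vol <- ceiling(max(ev$onset + ev$duration) / 1.056) + 5
  tls <- tapply(ev$target_level, ev$trial, function(x) x[1])
  mods <- list(time = time_modulator(ev),
               distance = distance_modulator(ev, tls))
  des <- build_design(ev, n_vol, 1.056, modulators = mods)
  Xt <- des$X[, "time"]; Xd <- des$X[, "distance"]
  # later modulator orthogonal to the earlier one and to condition boxcars
  expect_lt(abs(sum(Xt * Xd)) / sqrt(sum(Xt^2) * sum(Xd^2)), 1e-8)
  for (cc in des$condition_cols) {
    expect_lt(abs(sum(des$X[, cc] * Xd)), 1e-6)
  }
  # a constant modulator centers to zero and is dropped with a warning
  const <- data.frame(onset = c(10, 30), duration = 1, value = c(2, 2))
  expect_warning(
    d2 <- build_design(ev, n_vol, 1.056, modulators = list(flat = const)),
    "constant")
  expect_false("flat" %in% colnames(d2$X))
})

test_that("noiseless data are recovered exactly and residuals are orthogonal", {
  sc <- test_scale()
  ev <- test_session()$events[[1]]
  ev <- ev[ev$event_type != "press", ]
  n_vol <- ceiling(max(ev$onset + ev$duration) / 1.056) + 5
  des <- build_design(ev, n_vol, 1.056,
                      modulators = list(density = density_modulator(ev, sc)))
  set.seed(5)
  B_true <- matrix(rnorm(ncol(des$X) * 30), ncol(des$X), 30)
  Y <- des$X %*% B_true
  fit <- fit_glm(Y, des, ar1 = FALSE)
  expect_equal(unname(fit$betas), unname(B_true), tolerance = 1e-8)
  # with noise, OLS residuals are orthogonal to the design
  Yn <- Y + matrix(rnorm(length(Y)), nrow(Y))
  fitn <- fit_glm(Yn, des, ar1 = FALSE)
  expect_lt(max(abs(crossprod(des$X, fitn$residuals))), 1e-6)
})

test_that("condition contrasts combine betas with the stated weights", {
  sc <- test_scale()
  ev <- test_session()$events[[1]]
  ev <- ev[ev$event_type != "press", ]
  n_vol <- ceiling(max(ev$onset + ev$duration) / 1.056) + 5
  des <- build_design(ev, n_vol, 1.056)
  set.seed(6)
  Y <- des$X %*% matrix(1, ncol(des$X), 4)  # all-equal betas
  fit <- fit_glm(Y, des, ar1 = FALSE)
  memory <- c(MA = 1, MP = 1, "NA" = -1, NP = -1)
  adjust <- c(MA = 1, "NA" = 1, MP = -1, NP = -1)
  interaction <- c(MA = 1, MP = -1, "NA" = -1, NP = 1)
  for (w in list(memory, adjust, interaction)) {
    expect_equal(max(abs(contrast_map(fit, w))), 0, tolerance = 1e-8)
  }
  expect_warning(contrast_map(fit, c(MA = 1, MP = -0.5)), "sum to zero")
})

test_that("group inference masks zero-variance voxels", {
  maps <- rbind(c(1, 2, 0), c(1, 2.5, 0), c(1, 1.5, 0))
  gi <- group_inference(maps)
  expect_true(is.na(gi$t[1]))      # identical nonzero maps: infinite t
  expect_true(is.na(gi$t[3]))      # identically zero
  expect_equal(gi$df, 2L)
  expect_equal(gi$t[2], 2 / (0.5 / sqrt(3)))
})

test_that("cluster labeling uses 6-connectivity", {
  m <- array(FALSE, c(4, 4, 3))
  m[1:2, 1, 1] <- TRUE          # one face-connected pair
  m[4, 4, 3] <- TRUE            # isolated voxel
  m[3, 3, 1] <- TRUE; m[4, 4, 1] <- TRUE  # edge neighbors: NOT connected
  lab <- label_clusters(m)
  expect_identical(max(lab), 4L)
  expect_identical(lab[1, 1, 1], lab[2, 1, 1])
  expect_false(lab[3, 3, 1] == lab[4, 4, 1])
})

test_that("single-voxel small-volume correction is an uncorrected test", {
  mask <- array(TRUE, c(3, 3, 3))
  svc <- array(FALSE, c(3, 3, 3)); svc[2, 2, 2] <- TRUE
  set.seed(8)
  maps <- matrix(rnorm(10 * 27), 10, 27)
  res <- threshold_fwe(maps, mask, alpha = 0.05, method = "bonferroni",
                       svc_mask = svc, min_cluster = 1)
  expect_equal(res$threshold, qt(1 - 0.05 / 2, df = 9))
})

test_that("planted clusters survive FWE thresholding and are localized", {
  mask <- array(TRUE, c(8, 8, 6))
  roi <- array(FALSE, c(8, 8, 6)); roi[3:6, 3:6, 2:4] <- TRUE  # 48 voxels
  set.seed(9)
  maps <- matrix(rnorm(10 * sum(mask)), 10)
  maps[, roi[mask]] <- maps[, roi[mask]] + 1.5
  res <- threshold_fwe(maps, mask, alpha = 0.05, min_cluster = 5,
                       alternative = "greater", seed = 1)
  expect_gte(nrow(res$clusters), 1)
  pk <- res$clusters[which.max(res$clusters$peak_stat), ]
  expect_true(roi[pk$peak_x, pk$peak_y, pk$peak_z])
  expect_true(any(res$supra & roi))
})

test_that("AR(1) prewhitening recovers the autocorrelation", {
  sc <- test_scale()
  ev <- test_session()$events[[1]]
  ev <- ev[ev$event_type != "press", ]
  geom <- test_geom()
  spec <- effect_spec(ar1 = 0.4)
  subj <- generate_subject(geom, ev, spec, sc, seed = 3)
  des <- build_design(ev, subj$n_volumes, geom$grid$tr_s,
                      nuisance = subj$nuisance)
  fit <- fit_glm(bold_matrix(subj), des, ar1 = TRUE)
  # pooled lag-1 estimate from OLS residuals is biased slightly downward
  expect_lt(abs(fit$rho - 0.4), 0.08)
})
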
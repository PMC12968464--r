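test_that("responses follow the closed-form psychometric function", {
  obs <- psychometric_observer(sigma_log = 0.5)
  # zero difference: both responses equally likely
  set.seed(1)
  r0 <- replicate(4000, observer_respond(obs, 1, 1))
  expect_lt(abs(mean(r0 == "noisier") - 0.5), 0.03)
  # the 70.7% point of the closed form is hit empirically
  d707 <- sqrt(2) * obs$sigma_log * qnorm(sqrt(0.5))
  set.seed(2)
  r <- replicate(8000, observer_respond(obs, 0, d707))
  expect_lt(abs(mean(r == "noisier") - sqrt(0.5)), 0.02)
  # a huge difference is always judged correctly without lapses
  set.seed(3)
  r_inf <- replicate(50, observer_respond(obs, 0, 100))
  expect_true(all(r_inf == "noisier"))
  # lapses halve toward chance
  expect_equal(psychometric_p(psychometric_observer(1, 0.1), 1e9), 0.95)
})

test_that("staircase follows the two-down/one-up rule", {
  st <- staircase_state(9.1, start_delta_log = 1)
  st <- staircase_update(st, TRUE)
  expect_equal(st$delta_log, 1)           # one correct: no move yet
  st <- staircase_update(st, TRUE)
  expect_equal(st$delta_log, 1 - 1 / 3)   # two in a row: one step down
  expect_equal(st$n_correct_in_row, 0L)
  st <- staircase_update(st, FALSE)
  expect_equal(st$delta_log, 1)           # one error: one step up (reversal 1)
  expect_length(st$reversals, 1)
  expect_equal(st$step, 1 / 3)            # step unchanged until 2nd reversal
  st <- staircase_update(st, TRUE)
  st <- staircase_update(st, TRUE)        # down again: reversal 2
  expect_length(st$reversals, 2)
  expect_equal(st$step, 1 / 6)            # halved-step regime
  st <- staircase_update(st, TRUE)
  st <- staircase_update(st, TRUE)
  expect_equal(st$delta_log, 1 - 1 / 3 - 1 / 6)
})

test_that("staircase threshold shrinks to the step floor for an ideal observer", {
  # additive steps bound the resolution at half the final step size (1/12)
  obs <- psychometric_observer(sigma_log = 1e-4)
  thr <- vapply(1:10, function(s) run_staircase(obs, 9.1, seed = s)$threshold_log,
                numeric(1))
  expect_lt(mean(thr), 0.15)
  expect_lt(mean(9.1 * (exp(thr) - 1)), 9.1 * 0.17)
})

test_that("a Weber observer yields linear JNDs increasing with density", {
  obs <- psychometric_observer(sigma_log = 1.2)
  refs <- c(3.5, 9.1, 25.2, 66.5)
  jnd <- vapply(seq_along(refs), function(i) {
    mean(vapply(1:40, function(r) {
      run_staircase(obs, refs[i], seed = 1000 * i + r)$jnd
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(jnd) > 0))
})

test_that("noiseless navigation reaches the target exactly", {
  sc <- test_scale()
  obs <- navigation_observer(0, 0, 0)
  trial <- list(condition = "MA", start_level = 5L, target_level = 10L)
  out <- simulate_adjustment(obs, trial, sc, seed = 1)
  expect_identical(out$final_level, 10L)
  denser <- sum(out$presses$direction == "denser")
  sparser <- sum(out$presses$direction == "sparser")
  expect_identical(denser - sparser, 5L)  # exactly 5 net densifying steps
})

test_that("adjustment series move at most one level per stack", {
  sc <- test_scale()
  obs <- navigation_observer()
  for (s in 1:5) {
    trial <- list(condition = "MA", start_level = 20L, target_level = 8L)
    out <- simulate_adjustment(obs, trial, sc, seed = s)
    expect_true(all(abs(diff(out$series)) <= 1))
    # net signed presses equal net level change away from the boundaries
    if (all(out$series > 1 & out$series < 26)) {
      net <- sum(out$presses$direction == "denser") -
        sum(out$presses$direction == "sparser")
      expect_identical(out$final_level - trial$start_level, as.integer(net))
    }
  }
})

test_that("NA trials use the random matched-press policy", {
  sc <- test_scale()
  obs <- navigation_observer()
  trial <- list(condition = "NA", start_level = 13L, target_level = NA_integer_)
  out <- simulate_adjustment(obs, trial, sc, na_press_rate = 0.5, seed = 2)
  expect_length(out$series, 40)
  expect_true(nrow(out$presses) > 0)
  expect_error(simulate_adjustment(obs, list(condition = "MP"), sc), "adjustment")
  expect_error(simulate_adjustment(
    obs, list(condition = "MA", start_level = 3L, target_level = NA_integer_),
    sc), "target")
})

test_that("a calibrated noisy navigator behaves like a participant", {
  sc <- test_scale()
  obs <- navigation_observer()  # calibrated defaults
  set.seed(31)
  res <- t(replicate(200, {
    start <- sample(c(3:8, 18:24), 1)
    target <- if (start < 13) start + sample(5:12, 1) else start - sample(5:12, 1)
    trial <- list(condition = "MA", start_level = as.integer(start),
                  target_level = as.integer(target))
    out <- simulate_adjustment(obs, trial, sc)
    ns <- navigation_score(start, out$final_level, target)
    c(closer = ns$closer_than_start, under = isTRUE(ns$undershoot))
  }))
  expect_gt(mean(res[, "closer"]), 0.5)   # mostly ends closer to the target
  expect_gt(mean(res[, "under"]), 0)      # undershoot occurs
  expect_lt(mean(res[, "under"]), 1)
})

test_that("parity simulation respects lapse and miss rates", {
  digits <- data.frame(onset_s = 2:7, value = c(1, 2, 3, 4, 5, 6))
  perfect <- simulate_parity(0, digits, miss_rate = 0, seed = 1)
  expect_true(all(perfect$response == perfect$true_parity))
  none <- simulate_parity(0, digits, miss_rate = 1, seed = 2)
  expect_true(all(is.na(none$response)))
  set.seed(3)
  acc <- replicate(2000, {
    r <- simulate_parity(0.5, digits[1:3, ])
    mean(r$response == r$true_parity)
  })
  expect_lt(abs(mean(acc) - 0.75), 0.02)  # half guesses: 0.5 + 0.5/2
})
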
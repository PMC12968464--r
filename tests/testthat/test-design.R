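test_that("pair set spans the density space with balanced trajectories", {
  sc <- test_scale()
  ps <- make_pair_set(sc, seed = 1)
  expect_equal(nrow(ps), 28)
  expect_true(all(ps$start_level != ps$target_level))
  expect_equal(sum(ps$direction == "up"), 14)
  expect_equal(sum(ps$direction == "down"), 14)
  expect_true(all(abs(ps$start_level - ps$target_level) >= 5))
  expect_true(all((ps$direction == "up") == (ps$start_level < ps$target_level)))
  # targets stratified: 7 per quartile of the level range
  q <- cut(ps$target_level, breaks = round(seq(0, 26, length.out = 5)))
  expect_true(all(table(q) == 7))
})

test_that("digit slots lie on the free-second grid", {
  expect_setequal(slot_onsets(6, seed = 1), 2:7)
  o <- slot_onsets(1, seed = 2)
  expect_true(o %in% 2:7)
  expect_error(slot_onsets(7), "between 1 and 6")
  expect_error(slot_onsets(0), "between 1 and 6")
})

test_that("digit count rule adds, rounds stochastically and clamps", {
  expect_identical(digit_count_rule(3, 1.0), 4L)
  expect_identical(digit_count_rule(6, 2.0), 6L)
  expect_identical(digit_count_rule(0, NULL, seed = 1) %in% 1:6, TRUE)
  draws <- vapply(1:200, function(s) digit_count_rule(3, NULL, seed = s),
                  integer(1))
  expect_setequal(unique(draws), c(3L, 4L))
  expect_gt(mean(draws == 3L), 0.3)  # stochastic rounding hits both values
  expect_gt(mean(draws == 4L), 0.3)
})

test_that("runs satisfy the printed design structure", {
  sc <- test_scale()
  ps <- make_pair_set(sc, seed = 3)
  for (s in 1:3) {
    run <- build_run(ps, sc, seed = s)
    conds <- vapply(run$trials, `[[`, character(1), "condition")
    expect_length(conds, 28)
    expect_true(all(table(conds) == 7))
    expect_false(any(conds[-1] == conds[-28]))
    for (b in seq_len(7)) {
      set <- conds[run$set == b]
      expect_lt(which(set == "MA"), which(set == "NA"))
      expect_lt(which(set == "MP"), which(set == "NP"))
    }
    for (tr in run$trials) {
      expect_length(tr$initial_series, 10)
      info <- condition_info(tr$condition)
      if (info$has_memory) {
        expect_false(is.na(tr$target_level))
        expect_true(all(tr$initial_series == tr$target_level))
      } else {
        expect_true(is.na(tr$target_level))
        expect_setequal(unique(tr$initial_series), c(1L, 26L))
      }
      expect_true(tr$silence_s >= 1 && tr$silence_s <= 3)
      expect_true(tr$iti_s >= 0 && tr$iti_s <= 2)
      expect_true(nrow(tr$digits) >= 1 && nrow(tr$digits) <= 6)
      expect_true(all(tr$digits$onset_s %in% 2:7))
    }
  }
})

test_that("yoking copies adjustment series and digit streams", {
  sc <- test_scale()
  ps <- make_pair_set(sc, seed = 5)
  run <- build_run(ps, sc, seed = 5)
  conds <- vapply(run$trials, `[[`, character(1), "condition")
  obs <- navigation_observer()
  adjust_out <- list()
  for (i in which(conds %in% c("MA", "NA"))) {
    adjust_out[[as.character(i)]] <-
      simulate_adjustment(obs, run$trials[[i]], sc, seed = 100 + i)
  }
  run <- yoke_trials(run, adjust_out, seed = 9)
  for (i in seq_along(run$trials)) {
    tr <- run$trials[[i]]
    expect_length(tr$adjust_series, 40)
    if (tr$condition %in% c("MP", "NP") && !is.na(tr$yoke_source)) {
      src <- run$trials[[tr$yoke_source]]
      expect_identical(tr$adjust_series, src$adjust_series)
      expect_identical(src$condition, if (tr$condition == "MP") "MA" else "NA")
      expect_lt(tr$yoke_source, i)
    }
  }
  # digit yoking at build time: each MA copies the most recent MP stream
  for (i in which(conds == "MA")) {
    prev_mp <- which(conds == "MP" & seq_along(conds) < i)
    if (length(prev_mp)) {
      expect_identical(run$trials[[i]]$digits,
                       run$trials[[max(prev_mp)]]$digits)
    }
  }
  expect_error(yoke_trials(build_run(ps, sc, seed = 6), list()), "unresolved")
})

test_that("pooled adjust-phase densities match between yoked conditions", {
  sess <- test_session()
  run <- sess$runs[[1]]
  conds <- vapply(run$trials, `[[`, character(1), "condition")
  pooled <- function(cc) {
    sort(unlist(lapply(run$trials[conds %in% cc], `[[`, "adjust_series")))
  }
  # restrict to parity trials with a real (non-dummy) yoke source
  yoked <- vapply(run$trials, function(tr) !is.na(tr$yoke_source), logical(1))
  src <- vapply(run$trials[yoked], `[[`, integer(1), "yoke_source")
  a <- sort(unlist(lapply(run$trials[src], `[[`, "adjust_series")))
  p <- sort(unlist(lapply(run$trials[yoked], `[[`, "adjust_series")))
  expect_identical(a, p)
})

test_that("event tables round-trip through TSV", {
  sess <- test_session()
  ev <- sess$events[[1]]
  path <- tempfile(fileext = ".tsv")
  write_events(ev, path)
  back <- read_events(path)
  expect_identical(names(back), names(ev))
  expect_equal(back$onset, ev$onset, tolerance = 1e-8)
  expect_identical(back$event_type, ev$event_type)
  expect_identical(back$condition, ev$condition)
  expect_equal(back$density_level, ev$density_level)
  unlink(path)
})

test_that("trials expose 10 initial and 40 adjustment stacks in the events", {
  sess <- test_session()
  ev <- sess$events[[1]]
  counts <- table(ev$event_type[ev$event_type == "initial_stack"], ev$trial[ev$event_type == "initial_stack"])
  expect_true(all(counts == 10))
  counts2 <- table(ev$trial[ev$event_type == "adjust_stack"])
  expect_true(all(counts2 == 40))
})
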
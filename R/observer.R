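#' Psychometric observer for density discrimination
#'
#' A signal-detection observer for two-interval density comparison. Each
#' stack's log-density is perceived with independent Gaussian noise of
#' standard deviation `sigma_log`, so the difference estimate has SD
#' `sqrt(2) * sigma_log` and the probability of a correct "beepier"/"noisier"
#' judgement at true log-difference `delta` is
#' `(1 - lapse) * pnorm(|delta| / (sqrt(2) * sigma_log)) + lapse / 2`.
#'
#' @param sigma_log Discrimination noise in log-density units (> 0).
#' @param lapse_rate Lapse probability in \[0, 0.1\]: on a lapse the observer
#'   guesses uniformly.
#' @return Object of class `psychometric_observer`.
#' @export
psychometric_observer <- function(sigma_log, lapse_rate = 0) {
  if (!is.numeric(sigma_log) || sigma_log <= 0) {
    stop("sigma_log must be > 0", call. = FALSE)
  }
  if (lapse_rate < 0 || lapse_rate > 0.1) {
    stop("lapse_rate must lie in [0, 0.1]", call. = FALSE)
  }
  structure(list(sigma_log = sigma_log, lapse_rate = lapse_rate),
            class = "psychometric_observer")
}

#' Probability correct of a psychometric observer
#'
#' Closed form of the observer's psychometric function, used both by the
#' simulator and to evaluate staircase convergence.
#'
#' @param observer A [psychometric_observer()].
#' @param delta_log Absolute log-density difference between the two stacks.
#' @return Probability of a correct response.
#' @export
psychometric_p <- function(observer, delta_log) {
  (1 - observer$lapse_rate) *
    stats::pnorm(abs(delta_log) / (sqrt(2) * observer$sigma_log)) +
    observer$lapse_rate / 2
}

#' Simulate one "beepier"/"noisier" judgement
#'
#' @param observer A [psychometric_observer()].
#' @param ref_level_log,cmp_level_log Log densities of the first and second
#'   stack.
#' @param seed Optional seed.
#' @return `"noisier"` if the second stack is perceived as denser than the
#'   first, else `"beepier"`.
#' @export
observer_respond <- function(observer, ref_level_log, cmp_level_log,
                             seed = NULL) {
  stopifnot(inherits(observer, "psychometric_observer"))
  with_seed(seed, {
    if (stats::runif(1) < observer$lapse_rate) {
      return(sample(c("noisier", "beepier"), 1L))
    }
    d_hat <- (cmp_level_log - ref_level_log) +
      stats::rnorm(1, 0, sqrt(2) * observer$sigma_log)
    if (d_hat > 0) "noisier" else "beepier"
  })
}

#' Initialize a two-down/one-up staircase
#'
#' @param reference_density Reference density in tone components/octave.
#' @param start_delta_log Initial log-density difference (default 1).
#' @param step Initial step size (default 1/3; switches to 1/6 after the
#'   second reversal). Steps operate on the log of the density ratio between
#'   the two stacks.
#' @return Object of class `staircase_state`.
#' @export
staircase_state <- function(reference_density, start_delta_log = 1,
                            step = 1 / 3) {
  if (start_delta_log <= 0) stop("start_delta_log must be > 0", call. = FALSE)
  structure(
    list(delta_log = start_delta_log, n_correct_in_row = 0L,
         reversals = numeric(0), step = step,
         reference_density = reference_density,
         last_direction = NA_character_),
    class = "staircase_state"
  )
}

#' Two-down/one-up staircase update
#'
#' Two consecutive correct responses decrease the difference by the current
#' step (and reset the counter); one incorrect response increases it. A change
#' in movement direction appends the pre-step difference to the reversal list,
#' and the step size switches from 1/3 to 1/6 after the second reversal. The
#' rule converges on the 70.7% correct point of the psychometric function.
#'
#' @param state A [staircase_state()].
#' @param correct Logical: was the response correct?
#' @return Updated `staircase_state`.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"))
  move <- NULL
  if (correct) {
    state$n_correct_in_row <- state$n_correct_in_row + 1L
    if (state$n_correct_in_row >= 2L) {
      move <- "down"
      state$n_correct_in_row <- 0L
    }
  } else {
    move <- "up"
    state$n_correct_in_row <- 0L
  }
  if (!is.null(move)) {
    step_now <- state$step  # the move at the 2nd reversal still uses 1/3
    if (!is.na(state$last_direction) && move != state$last_direction) {
      state$reversals <- c(state$reversals, state$delta_log)
      if (length(state$reversals) == 2L) state$step <- 1 / 6
    }
    state$last_direction <- move
    delta <- if (move == "down") state$delta_log - step_now
             else state$delta_log + step_now
    state$delta_log <- max(delta, 1e-6)
  }
  state
}

#' Run an adaptive staircase to estimate a density JND
#'
#' Simulates trials of the two-interval discrimination task, tracking the
#' log-density difference with the two-down/one-up rule until six reversals
#' occur. The threshold is the mean difference over the final two reversals,
#' also expressed as a just-noticeable difference in components/octave at the
#' reference density (`jnd = reference * (exp(threshold_log) - 1)`).
#'
#' @param observer A [psychometric_observer()].
#' @param reference_density Reference density (components/octave).
#' @param start_delta_log Initial log difference (default 1).
#' @param n_reversals Reversals to collect (default 6; threshold averages the
#'   final two).
#' @param max_trials Trial cap before declaring non-convergence (default 200).
#' @param seed Optional seed.
#' @return List with `threshold_log`, `jnd`, `reference_density`, `n_trials`,
#'   `reversals`.
#' @export
run_staircase <- function(observer, reference_density, start_delta_log = 1,
                          n_reversals = 6L, max_trials = 200L, seed = NULL) {
  stopifnot(inherits(observer, "psychometric_observer"))
  with_seed(seed, {
    st <- staircase_state(reference_density, start_delta_log)
    n <- 0L
    while (length(st$reversals) < n_reversals) {
      n <- n + 1L
      if (n > max_trials) stop("staircase did not converge", call. = FALSE)
      correct <- stats::runif(1) < psychometric_p(observer, st$delta_log)
      st <- staircase_update(st, correct)
    }
    thr <- mean(st$reversals[(n_reversals - 1L):n_reversals])
    list(threshold_log = thr,
         jnd = reference_density * (exp(thr) - 1),
         reference_density = reference_density,
         n_trials = n,
         reversals = st$reversals)
  })
}

#' Navigating observer for the adjustment task
#'
#' An agent generating the button-press behavior of the MA/NA adjustment
#' phase. It stores the target log-density with Gaussian memory noise, reads
#' the current level with perceptual noise, and while the perceived distance
#' to the remembered target exceeds `stop_criterion` holds the button that
#' moves the density one scale level per 200-ms stack toward the target.
#'
#' @param memory_sigma SD of the noise on the stored target (log-density
#'   units, i.e. units of log(2)-spaced scale steps are `log(max/min)/(L-1)`).
#' @param perceive_sigma SD of the noise on the currently heard density.
#' @param stop_criterion Perceived |distance| (log units) below which the
#'   agent stops pressing.
#' @param press_latency_s Latency from stack onset to press (default 0.1 s).
#' @return Object of class `navigation_observer`.
#' @export
navigation_observer <- function(memory_sigma = 0.45, perceive_sigma = 0.15,
                                stop_criterion = 0.6, press_latency_s = 0.1) {
  if (any(c(memory_sigma, perceive_sigma, stop_criterion, press_latency_s) < 0)) {
    stop("observer parameters must be nonnegative", call. = FALSE)
  }
  structure(list(memory_sigma = memory_sigma, perceive_sigma = perceive_sigma,
                 stop_criterion = stop_criterion,
                 press_latency_s = press_latency_s),
            class = "navigation_observer")
}

#' Simulate the 8-s adjustment phase of an MA or NA trial
#'
#' The density series starts at the trial's start level; a held press moves it
#' one scale level per 200-ms stack (clipped at the scale boundaries, no
#' wraparound). In MA trials the agent presses toward its noisy memory of the
#' target until the perceived distance falls below its stop criterion; in NA
#' trials (no target) it executes a random press policy with per-stack press
#' probability `na_press_rate` and a direction that persists with switching
#' probability 0.2, emulating the instruction to adjust at will with a similar
#' number of presses.
#'
#' @param observer A [navigation_observer()].
#' @param trial A trial from [build_run()] with condition MA or NA.
#' @param scale The density scale.
#' @param na_press_rate Per-stack press probability for NA trials; calibrate
#'   to the observed MA press rate to match press counts.
#' @param seed Optional seed.
#' @return List with `presses` (data frame: stack, onset_s within the phase,
#'   direction in \{"denser","sparser"\}), `series` (40 level indices) and
#'   `final_level`.
#' @export
simulate_adjustment <- function(observer, trial, scale, na_press_rate = 0.5,
                                seed = NULL) {
  stopifnot(inherits(observer, "navigation_observer"),
            inherits(scale, "density_scale"))
  if (!condition_info(trial$condition)$has_adjust) {
    stop("trial is not an adjustment (MA/NA) trial", call. = FALSE)
  }
  is_ma <- trial$condition == "MA"
  if (is_ma && is.na(trial$target_level)) {
    stop("MA trial requires a target level", call. = FALSE)
  }
  log_levels <- log(scale$levels)
  with_seed(seed, {
    target_mem <- if (is_ma) {
      log_levels[trial$target_level] + stats::rnorm(1, 0, observer$memory_sigma)
    } else NA_real_
    lv <- trial$start_level
    series <- integer(N_ADJUST_STACKS)
    press_stack <- integer(0); press_dir <- character(0)
    na_dir <- sample(c(1L, -1L), 1L)
    stopped <- FALSE  # once satisfied, the agent commits and stops adjusting
    for (t in seq_len(N_ADJUST_STACKS)) {
      series[t] <- lv
      step <- 0L
      if (is_ma) {
        if (!stopped) {
          perceived <- log_levels[lv] +
            stats::rnorm(1, 0, observer$perceive_sigma)
          dist <- target_mem - perceived
          if (abs(dist) >= observer$stop_criterion) {
            step <- as.integer(sign(dist))
          }
          else stopped <- TRUE
        }
      } else {
        if (stats::runif(1) < 0.2) na_dir <- -na_dir
        if (stats::runif(1) < na_press_rate) step <- na_dir
      }
      if (step != 0L) {
        press_stack <- c(press_stack, t)
        press_dir <- c(press_dir, if (step > 0) "denser" else "sparser")
        lv <- max(1L, min(scale$n_levels, lv + step))
      }
    }
    list(presses = data.frame(
           stack = press_stack,
           onset_s = (press_stack - 1L) * 0.2 + observer$press_latency_s,
           direction = press_dir, stringsAsFactors = FALSE),
         series = series,
         final_level = lv)
  })
}

#' Simulate parity (odd/even) responses to a digit stream
#'
#' Each presented digit is missed with probability `miss_rate`; otherwise a
#' response is produced after `rt_mean_s` (plus noise), correct with
#' probability `1 - lapse_rate/2` (on a lapse the observer guesses the parity
#' uniformly).
#'
#' @param lapse_rate Guessing probability in \[0, 1\].
#' @param digits Data frame with columns `onset_s` and `value` (1-10).
#' @param miss_rate Probability of no response per digit (default 0).
#' @param rt_mean_s,rt_sd_s Response-time distribution after digit onset.
#' @param seed Optional seed.
#' @return Data frame: `onset_s`, `value`, `true_parity`, `response`
#'   (`"odd"`/`"even"`/`NA`), `rt_s`.
#' @export
simulate_parity <- function(lapse_rate, digits, miss_rate = 0,
                            rt_mean_s = 0.8, rt_sd_s = 0.15, seed = NULL) {
  if (lapse_rate < 0 || lapse_rate > 1) stop("lapse_rate in [0,1]", call. = FALSE)
  if (miss_rate < 0 || miss_rate > 1) stop("miss_rate in [0,1]", call. = FALSE)
  n <- nrow(digits)
  with_seed(seed, {
    true_par <- ifelse(digits$value %% 2L == 1L, "odd", "even")
    responded <- stats::runif(n) >= miss_rate
    lapse <- stats::runif(n) < lapse_rate
    guess <- sample(c("odd", "even"), n, replace = TRUE)
    resp <- ifelse(lapse, guess, true_par)
    resp[!responded] <- NA_character_
    rt <- pmax(0.15, stats::rnorm(n, rt_mean_s, rt_sd_s))
    rt[!responded] <- NA_real_
    data.frame(onset_s = digits$onset_s, value = digits$value,
               true_parity = true_par, response = resp, rt_s = rt,
               stringsAsFactors = FALSE)
  })
}
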
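#' Condition codes of the two-by-two design
#'
#' The design crosses a memory factor (hold a target density in mind: M, or
#' not: N) with a task factor during the 8-s phase (adjust the tone stream: A,
#' or judge digit parity: P), giving MA, MP, NA, NP.
#'
#' @param code One of "MA", "MP", "NA", "NP".
#' @return List with `code`, `has_memory`, `has_adjust`.
#' @export
condition_info <- function(code) {
  code <- match.arg(code, c("MA", "MP", "NA", "NP"))
  list(code = code,
       has_memory = substr(code, 1, 1) == "M",
       has_adjust = substr(code, 2, 2) == "A")
}

N_INITIAL_STACKS <- 10L  # 2-s initial sound
N_ADJUST_STACKS <- 40L   # 8-s adjustment/parity phase
DIGIT_SLOTS <- 2:7       # onsets (s) within the 8-s phase; first/last second free

#' Build the predetermined set of start/target density pairs
#'
#' The experiment draws its trajectories from 28 predetermined
#' (start, target) level pairs that span the density space with equal
#' sampling of high- and low-density sounds. The published set is not listed,
#' so one consistent instantiation is constructed: targets are stratified
#' into the four quartiles of the level range (7 per quartile); pairs with
#' targets in the lower half run downward (start above target) and pairs in
#' the upper half run upward, giving 14 upward and 14 downward trajectories,
#' all with `|start - target| >= min_separation`.
#'
#' @param scale A [make_density_scale()] object with >= 4 levels.
#' @param n_pairs Number of pairs (default 28).
#' @param min_separation Minimum |start - target| in levels (default 5).
#' @param seed Optional seed.
#' @return Data frame with columns `start_level`, `target_level`, `direction`
#'   (`"up"` or `"down"`), class `pair_set`.
#' @export
make_pair_set <- function(scale, n_pairs = 28L, min_separation = 5L, seed = NULL) {
  stopifnot(inherits(scale, "density_scale"))
  if (scale$n_levels < 4L) stop("scale must have >= 4 levels", call. = FALSE)
  n_pairs <- as.integer(n_pairs)
  if (n_pairs %% 4L != 0L) stop("n_pairs must be a multiple of 4", call. = FALSE)
  L <- scale$n_levels
  min_separation <- min(as.integer(min_separation), L - 1L)
  with_seed(seed, {
    # quartile bins of the level index range
    edges <- round(seq(0, L, length.out = 5))
    per_q <- n_pairs %/% 4L
    targets <- unlist(lapply(seq_len(4), function(q) {
      lo <- edges[q] + 1L; hi <- edges[q + 1L]
      # keep targets feasible for the direction the half dictates
      if (q <= 2) lo <- max(lo, 1L) else hi <- min(hi, L)
      sample(seq.int(lo, hi), per_q, replace = per_q > (hi - lo + 1L))
    }))
    direction <- rep(c("down", "up"), each = n_pairs %/% 2L)  # low targets: down
    starts <- vapply(seq_len(n_pairs), function(i) {
      tg <- targets[i]
      cand <- if (direction[i] == "up") {
        seq_len(max(tg - min_separation, 1L))
      } else {
        seq.int(min(tg + min_separation, L), L)
      }
      cand <- setdiff(cand, tg)
      if (direction[i] == "up") cand <- cand[cand < tg] else cand <- cand[cand > tg]
      if (length(cand) == 0) {
        # fall back to the nearest feasible start in the required direction
        if (direction[i] == "up") tg - 1L else tg + 1L
      } else {
        cand[sample.int(length(cand), 1L)]
      }
    }, integer(1))
    structure(
      data.frame(start_level = starts, target_level = targets,
                 direction = direction, stringsAsFactors = FALSE),
      class = c("pair_set", "data.frame")
    )
  })
}

#' Number of digits for a parity trial
#'
#' Button presses are matched across conditions by setting the digit count of
#' each parity (MP/NP) trial to the press count proxy of the previous
#' adjustment (MA/NA) trial plus the mean number of unanswered digits across
#' all previous parity trials of the block (0.5 when none are available),
#' rounded up or down at random when fractional, and clamped to the 1..6
#' admissible slots.
#'
#' @param prev_adjust_digit_count Digit count of the previous MA/NA trial (>= 0).
#' @param mean_unanswered Running mean of unanswered digits, or `NULL` at block
#'   start.
#' @param seed Optional seed for the stochastic rounding.
#' @return Integer in 1..6.
#' @export
digit_count_rule <- function(prev_adjust_digit_count, mean_unanswered = NULL,
                             seed = NULL) {
  if (prev_adjust_digit_count < 0) stop("digit count must be >= 0", call. = FALSE)
  x <- prev_adjust_digit_count + (mean_unanswered %||% 0.5)
  frac <- x - floor(x)
  n <- with_seed(seed, {
    if (frac == 0) x else floor(x) + (stats::runif(1) < 0.5)
  })
  as.integer(max(1L, min(6L, n)))
}

#' Draw digit onset slots within the 8-s phase
#'
#' Digits occupy slots starting at one-second intervals from second two,
#' leaving the first and final second free, i.e. onsets in \{2,...,7\} s.
#'
#' @param n_digits Number of digits, 1..6.
#' @param seed Optional seed.
#' @return Sorted integer onsets (seconds within the phase).
#' @export
slot_onsets <- function(n_digits, seed = NULL) {
  n_digits <- as.integer(n_digits)
  if (n_digits < 1L || n_digits > 6L) {
    stop("n_digits must be between 1 and 6", call. = FALSE)
  }
  with_seed(seed, sort(sample(DIGIT_SLOTS, n_digits)))
}

random_digits <- function(n, seed = NULL) {
  with_seed(seed, data.frame(
    onset_s = slot_onsets(n),
    value = sample(1:10, n, replace = TRUE),
    voice = sample(c("male", "female"), n, replace = TRUE),
    stringsAsFactors = FALSE
  ))
}

new_trial <- function(condition, start_level, target_level, initial_series,
                      silence_s, digits, iti_s) {
  list(condition = condition,
       start_level = start_level,
       target_level = target_level,       # NA_integer_ for NA/NP
       initial_series = initial_series,   # 10 level indices
       silence_s = silence_s,             # maintenance silence, U[1,3]
       adjust_series = NULL,              # 40 levels, resolved by simulation/yoking
       digits = digits,                   # data.frame(onset_s, value, voice)
       n_unanswered = NA_real_,           # filled by simulation
       rating_window_s = 3,
       iti_s = iti_s,
       yoke_source = NA_integer_)
}

order_one_set <- function() {
  repeat {
    ord <- sample(c("MA", "MP", "NA", "NP"))
    if (which(ord == "MA") < which(ord == "NA") &&
        which(ord == "MP") < which(ord == "NP")) return(ord)
  }
}

#' Generate one fully resolved run of 28 trials
#'
#' A run comprises seven sets of four trials, one per condition. Within each
#' set the MA trial precedes the NA trial and the MP trial precedes the NP
#' trial; across the whole run no two consecutive trials share a condition.
#' MA/MP trials draw a (start, target) pair from the pair set; NA/NP trials
#' use the start level only. The 2-s initial sound is ten stacks at the target
#' level (M conditions) or alternating between the lowest and highest level
#' (N conditions). Maintenance silences are uniform on \[1, 3\] s and
#' inter-trial intervals uniform on \[0, 2\] s. Digit streams are resolved
#' with the press-matching count rule and the yoking of digit identity from
#' parity to adjustment trials (seeded dummy trials bootstrap streams with no
#' predecessor).
#'
#' @param pair_set A [make_pair_set()] result with at least 28 rows.
#' @param scale The density scale.
#' @param seed Optional seed.
#' @param history Optional list of prior trials (with `n_unanswered` filled by
#'   simulation) used to seed the digit-count rule's running mean; the mean is
#'   otherwise the 0.5 block-start fallback.
#' @return An object of class `nav_run`: list of 28 trials plus `set` index.
#' @export
build_run <- function(pair_set, scale, seed = NULL, history = NULL) {
  stopifnot(inherits(pair_set, "pair_set"), inherits(scale, "density_scale"))
  n_sets <- 7L
  if (nrow(pair_set) < 4L * n_sets) stop("pair set too small", call. = FALSE)
  with_seed(seed, {
    # condition order: retry until no condition repeats across set boundaries
    for (attempt in seq_len(1000L)) {
      conds <- unlist(lapply(seq_len(n_sets), function(i) order_one_set()))
      if (!any(conds[-1] == conds[-length(conds)])) break
      if (attempt == 1000L) stop("could not satisfy ordering constraints")
    }
    pairs <- pair_set[sample.int(nrow(pair_set), 4L * n_sets), ]
    unanswered <- vapply(history %||% list(), function(tr) tr$n_unanswered,
                         numeric(1))
    unanswered <- unanswered[!is.na(unanswered)]
    last_adjust_count <- NA_integer_
    last_parity_digits <- list(MA = NULL, NA_ = NULL)  # from MP / NP
    trials <- vector("list", 4L * n_sets)
    for (i in seq_along(conds)) {
      code <- conds[i]
      info <- condition_info(code)
      start <- pairs$start_level[i]
      target <- if (info$has_memory) pairs$target_level[i] else NA_integer_
      initial <- if (info$has_memory) {
        rep(target, N_INITIAL_STACKS)
      } else {
        alt <- rep(c(1L, scale$n_levels), length.out = N_INITIAL_STACKS)
        if (stats::runif(1) < 0.5) alt else rev(alt)
      }
      if (info$has_adjust) {
        src <- if (code == "MA") last_parity_digits$MA else last_parity_digits$NA_
        digits <- src %||% random_digits(sample(1:6, 1L))
      } else {
        prev_count <- if (is.na(last_adjust_count)) sample(1:6, 1L) else last_adjust_count
        mu <- if (length(unanswered)) mean(unanswered) else NULL
        digits <- random_digits(digit_count_rule(prev_count, mu))
      }
      tr <- new_trial(code, start, target, initial,
                      silence_s = stats::runif(1, 1, 3), digits = digits,
                      iti_s = stats::runif(1, 0, 2))
      if (info$has_adjust) {
        last_adjust_count <- nrow(digits)
      } else if (code == "MP") {
        last_parity_digits$MA <- digits
      } else {
        last_parity_digits$NA_ <- digits
      }
      trials[[i]] <- tr
    }
    structure(list(trials = trials,
                   set = rep(seq_len(n_sets), each = 4L),
                   scale = scale),
              class = "nav_run")
  })
}

#' @export
print.nav_run <- function(x, ...) {
  conds <- vapply(x$trials, `[[`, character(1), "condition")
  cat(sprintf("<nav_run> %d trials (%s)\n", length(x$trials),
              paste(conds, collapse = " ")))
  invisible(x)
}

# random-walk dummy adjust series used to bootstrap yoking at block start
dummy_adjust_series <- function(start_level, scale) {
  lv <- start_level
  out <- integer(N_ADJUST_STACKS)
  for (t in seq_len(N_ADJUST_STACKS)) {
    out[t] <- lv
    step <- sample(c(-1L, 0L, 1L), 1L)
    lv <- max(1L, min(scale$n_levels, lv + step))
  }
  out
}

#' Copy adjustment-phase density series into yoked parity trials
#'
#' After observer simulation resolves the 40-stack density series of each
#' MA/NA trial, every MP trial receives the series of the most recent MA
#' trial and every NP trial that of the most recent NA trial, so that the
#' parity conditions are acoustically matched to the adjustment conditions.
#' A parity trial with no preceding adjustment trial of the matching memory
#' status takes a seeded dummy random-walk series.
#'
#' @param run A `nav_run`.
#' @param adjust_outputs Named list indexed by trial number (as character) of
#'   [simulate_adjustment()] results for all MA/NA trials.
#' @param seed Optional seed for dummy bootstrap series.
#' @return The run with every trial's `adjust_series` resolved and
#'   `yoke_source` recorded on parity trials.
#' @export
yoke_trials <- function(run, adjust_outputs, seed = NULL) {
  stopifnot(inherits(run, "nav_run"))
  with_seed(seed, {
    last_series <- list(MP = NULL, NP = NULL)  # from MA / NA
    last_idx <- list(MP = NA_integer_, NP = NA_integer_)
    for (i in seq_along(run$trials)) {
      tr <- run$trials[[i]]
      if (condition_info(tr$condition)$has_adjust) {
        out <- adjust_outputs[[as.character(i)]]
        if (is.null(out) || is.null(out$series)) {
          stop(sprintf("unresolved adjustment series for trial %d", i),
               call. = FALSE)
        }
        run$trials[[i]]$adjust_series <- out$series
        key <- if (tr$condition == "MA") "MP" else "NP"
        last_series[[key]] <- out$series
        last_idx[[key]] <- i
      } else {
        key <- tr$condition
        if (is.null(last_series[[key]])) {
          run$trials[[i]]$adjust_series <- dummy_adjust_series(tr$start_level,
                                                               run$scale)
        } else {
          run$trials[[i]]$adjust_series <- last_series[[key]]
          run$trials[[i]]$yoke_source <- last_idx[[key]]
        }
      }
    }
    run
  })
}

#' Timing of trial phases
#'
#' Each trial: 2 s instruction silence, 2 s initial sound (10 stacks),
#' 1-3 s maintenance silence, 8 s adjustment/parity phase (40 stacks +
#' digits), 3 s rating window, 0-2 s inter-trial interval.
#'
#' @param trial A trial list from a `nav_run`.
#' @return Named list of phase onsets (s, trial-relative) and total duration.
#' @export
trial_phase_times <- function(trial) {
  instr <- 0
  initial <- 2
  silence <- initial + 0.2 * length(trial$initial_series)
  adjust <- silence + trial$silence_s
  rating <- adjust + 8
  list(instruction = instr, initial = initial, silence = silence,
       adjust = adjust, rating = rating,
       total = rating + trial$rating_window_s + trial$iti_s)
}

#' Serialize a run to a BIDS-events-like table
#'
#' One row per event: instruction, initial stacks, adjustment stacks, digits
#' and rating windows, with onsets in seconds from run start.
#'
#' @param run A `nav_run` (adjust series need not be resolved; unresolved
#'   stacks carry `NA` density).
#' @return Data frame with columns `onset`, `duration`, `event_type`, `trial`,
#'   `condition`, `density_level`, `target_level`, `digit_value`, `voice`.
#' @export
as_event_table <- function(run) {
  stopifnot(inherits(run, "nav_run"))
  rows <- list()
  t0 <- 0
  for (i in seq_along(run$trials)) {
    tr <- run$trials[[i]]
    ph <- trial_phase_times(tr)
    add <- function(onset, duration, type, level = NA_integer_,
                    value = NA_integer_, voice = NA_character_) {
      rows[[length(rows) + 1L]] <<- data.frame(
        onset = t0 + onset, duration = duration, event_type = type,
        trial = i, condition = tr$condition, density_level = level,
        target_level = tr$target_level, digit_value = value, voice = voice,
        stringsAsFactors = FALSE)
    }
    add(ph$instruction, 2, "instruction")
    for (k in seq_along(tr$initial_series)) {
      add(ph$initial + 0.2 * (k - 1), 0.19, "initial_stack",
          level = tr$initial_series[k])
    }
    adj <- tr$adjust_series %||% rep(NA_integer_, N_ADJUST_STACKS)
    for (k in seq_len(N_ADJUST_STACKS)) {
      add(ph$adjust + 0.2 * (k - 1), 0.19, "adjust_stack", level = adj[k])
    }
    if (nrow(tr$digits) > 0) {
      for (k in seq_len(nrow(tr$digits))) {
        add(ph$adjust + tr$digits$onset_s[k], 0.4, "digit",
            value = tr$digits$value[k], voice = tr$digits$voice[k])
      }
    }
    add(ph$rating, tr$rating_window_s, "rating")
    t0 <- t0 + ph$total
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read an event table as tab-separated values
#'
#' @param events Event table data frame.
#' @param path File path.
#' @return `path` (write) or the event table (read).
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = "n/a",
                    stringsAsFactors = FALSE)
}
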
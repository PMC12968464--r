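#' Simulate a complete experimental session for one participant
#'
#' Builds the requested number of runs, simulates the navigating observer on
#' every MA/NA trial (calibrating the NA press rate to the running MA press
#' rate), yokes the adjustment-phase series into the parity trials, simulates
#' parity responses and ratings, and scores every trial.
#'
#' @param scale A [make_density_scale()] object.
#' @param nav_observer A [navigation_observer()].
#' @param n_runs Number of runs (default 4).
#' @param parity_lapse,parity_miss Parity observer parameters (defaults 0.1
#'   and 0.05).
#' @param rating_sigma SD of the noise on the latent rating variable
#'   (default 0.5; rating responses are the latent quantity binned into 1-4).
#' @param rating_miss Probability of a missing rating (default 0.05).
#' @param seed Optional seed.
#' @return List of class `session`: `runs` (yoked `nav_run`s), `events`
#'   (per-run event tables including press events), `trial_scores` (data
#'   frame across runs).
#' @export
simulate_session <- function(scale, nav_observer = navigation_observer(),
                             n_runs = 4L, parity_lapse = 0.1,
                             parity_miss = 0.05, rating_sigma = 0.5,
                             rating_miss = 0.05, seed = NULL) {
  with_seed(seed, {
    pairs <- make_pair_set(scale)
    runs <- vector("list", n_runs)
    events <- vector("list", n_runs)
    scores <- list()
    ma_press_counts <- integer(0)
    for (r in seq_len(n_runs)) {
      run <- build_run(pairs, scale)
      adjust_out <- list()
      for (i in seq_along(run$trials)) {
        tr <- run$trials[[i]]
        if (!condition_info(tr$condition)$has_adjust) next
        rate <- if (length(ma_press_counts)) {
          min(1, mean(ma_press_counts) / N_ADJUST_STACKS)
        } else 0.5
        out <- simulate_adjustment(nav_observer, tr, scale,
                                   na_press_rate = rate)
        if (tr$condition == "MA") {
          ma_press_counts <- c(ma_press_counts, nrow(out$presses))
        }
        adjust_out[[as.character(i)]] <- out
      }
      run <- yoke_trials(run, adjust_out)
      for (i in seq_along(run$trials)) {
        tr <- run$trials[[i]]
        info <- condition_info(tr$condition)
        row <- data.frame(run = r, trial = i, condition = tr$condition,
                          start_level = tr$start_level,
                          target_level = tr$target_level,
                          final_level = NA_integer_,
                          final_distance = NA_integer_,
                          closer_than_start = NA, undershoot = NA,
                          n_presses = NA_integer_,
                          parity_accuracy = NA_real_,
                          n_unanswered = NA_real_,
                          rating = NA_integer_, rating_true = NA_real_)
        if (info$has_adjust) {
          out <- adjust_out[[as.character(i)]]
          row$final_level <- out$final_level
          row$n_presses <- nrow(out$presses)
          if (info$has_memory) {
            ns <- navigation_score(tr$start_level, out$final_level,
                                   tr$target_level)
            row$final_distance <- ns$final_distance_steps
            row$closer_than_start <- ns$closer_than_start
            row$undershoot <- ns$undershoot
          }
        } else {
          pr <- simulate_parity(parity_lapse, tr$digits,
                                miss_rate = parity_miss)
          run$trials[[i]]$n_unanswered <- sum(is.na(pr$response))
          row$n_unanswered <- sum(is.na(pr$response))
          row$parity_accuracy <- parity_score(
            pr$true_parity, pr$response[!is.na(pr$response)])
          row$n_presses <- sum(!is.na(pr$response))
        }
        # rating: memory trials rate closeness (4 = very different),
        # non-memory trials rate final density (4 = very noisy)
        final_lv <- row$final_level
        if (is.na(final_lv)) {
          final_lv <- tr$adjust_series[length(tr$adjust_series)]
        }
        truth <- if (info$has_memory) {
          abs(log(scale$levels[final_lv]) -
                log(scale$levels[tr$target_level]))
        } else {
          log(scale$levels[final_lv])
        }
        row$rating_true <- truth
        if (stats::runif(1) >= rating_miss) {
          span <- if (info$has_memory) {
            c(0, log(scale$max_tones / scale$min_tones) / 2)
          } else {
            log(c(scale$min_tones, scale$max_tones))
          }
          latent <- (truth - span[1]) / diff(span) +
            stats::rnorm(1, 0, rating_sigma)
          row$rating <- max(1L, min(4L, 1L + floor(4 * latent)))
        }
        scores[[length(scores) + 1L]] <- row
      }
      runs[[r]] <- run
      ev <- as_event_table(run)
      # append press events
      press_rows <- do.call(rbind, lapply(names(adjust_out), function(nm) {
        i <- as.integer(nm)
        out <- adjust_out[[nm]]
        if (nrow(out$presses) == 0) return(NULL)
        ph <- trial_phase_times(run$trials[[i]])
        trial_onset <- min(ev$onset[ev$trial == i])
        data.frame(onset = trial_onset + ph$adjust + out$presses$onset_s,
                   duration = 0, event_type = "press", trial = i,
                   condition = run$trials[[i]]$condition,
                   density_level = NA_integer_,
                   target_level = run$trials[[i]]$target_level,
                   digit_value = NA_integer_,
                   voice = out$presses$direction, stringsAsFactors = FALSE)
      }))
      if (!is.null(press_rows)) ev <- rbind(ev, press_rows)
      events[[r]] <- ev[order(ev$onset), ]
    }
    structure(list(runs = runs, events = events,
                   trial_scores = do.call(rbind, scores)),
              class = "session")
  })
}

#' Per-subject behavioral summary
#'
#' @param session A [simulate_session()] result.
#' @return One-row data frame: proportion of MA trials ending closer than the
#'   start, mean final distance (levels and as a fraction of the scale),
#'   undershoot proportion, parity accuracy by condition, and rating
#'   accuracies (Spearman, memory trials use negative closeness so that
#'   higher ratings mean more different).
#' @export
summarize_session <- function(session) {
  ts <- session$trial_scores
  ma <- ts[ts$condition == "MA", ]
  n_levels <- length(session$runs[[1]]$scale$levels)
  rating_rho <- function(cond) {
    s <- ts[ts$condition == cond, ]
    rating_accuracy(s$rating, s$rating_true)
  }
  data.frame(
    prop_closer = mean(ma$closer_than_start),
    mean_final_distance = mean(ma$final_distance),
    mean_final_distance_frac = mean(ma$final_distance) / (n_levels - 1),
    prop_undershoot = mean(ma$undershoot[!is.na(ma$undershoot)]),
    parity_mp = mean(ts$parity_accuracy[ts$condition == "MP"], na.rm = TRUE),
    parity_np = mean(ts$parity_accuracy[ts$condition == "NP"], na.rm = TRUE),
    rho_ma = rating_rho("MA"), rho_mp = rating_rho("MP"),
    rho_na = rating_rho("NA"), rho_np = rating_rho("NP")
  )
}
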
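#' Score navigation success on one adjustment trial
#'
#' Navigation success is the absolute number of steps in density space between
#' the final adjusted level and the target. Also reports whether the final
#' level is closer to the target than the start was, and whether the trial is
#' an undershoot (final level on the same side of the target as the start,
#' without reaching it).
#'
#' @param start_level,final_level,target_level Level indices on one scale.
#' @return List: `final_distance_steps`, `closer_than_start`, `undershoot`
#'   (`NA` when start == target).
#' @export
navigation_score <- function(start_level, final_level, target_level) {
  d_final <- abs(final_level - target_level)
  d_start <- abs(start_level - target_level)
  undershoot <- if (start_level == target_level) {
    NA
  } else {
    final_level != target_level &&
      sign(final_level - target_level) == sign(start_level - target_level)
  }
  list(final_distance_steps = as.integer(d_final),
       closer_than_start = d_final < d_start,
       undershoot = undershoot)
}

# All alignments of responses to digits that reconcile one extra or one
# missing response: a list of index vectors m with m[i] = digit aligned to
# response i (NA = unaligned).
parity_alignments <- function(n_d, n_r) {
  if (n_r == n_d) {
    return(list(seq_len(n_r)))
  }
  out <- list()
  if (n_r > n_d) {
    # one extra response at position k: responses after k shift back by one
    for (k in seq_len(n_r)) {
      m <- rep(NA_integer_, n_r)
      before <- seq_len(k - 1L)
      before <- before[before <= n_d]
      m[before] <- before
      after <- seq.int(k + 1L, length.out = n_r - k)
      m[after] <- ifelse(after - 1L <= n_d, after - 1L, NA_integer_)
      out[[length(out) + 1L]] <- m
    }
  } else {
    # one missing response after position k-1: digit k unanswered,
    # responses from k on shift forward by one
    for (k in seq_len(n_d)) {
      m <- seq_len(n_r)
      shift <- m >= k
      m[shift] <- m[shift] + 1L
      m[m > n_d] <- NA_integer_
      out[[length(out) + 1L]] <- m
    }
  }
  out
}

#' Dislocation-tolerant parity accuracy
#'
#' Parity judgements are scored as the number of matches divided by the larger
#' of the number of digits presented and the number of responses made. When an
#' extra or a missing response has dislocated the response series (i.e. the
#' two counts differ), matches are maximized over all alignments that drop one
#' spurious response or skip one unanswered digit; with equal counts the
#' alignment is positional. No responses scores 0.
#'
#' @param digit_parities Character/logical vector of presented parities (in
#'   order), e.g. `c("odd", "even", ...)`.
#' @param response_parities Response parities in order (may be shorter,
#'   longer, or empty).
#' @return Score in \[0, 1\].
#' @export
parity_score <- function(digit_parities, response_parities) {
  n_d <- length(digit_parities)
  n_r <- length(response_parities)
  if (n_r == 0L || n_d == 0L) return(0)
  matches <- vapply(parity_alignments(n_d, n_r), function(m) {
    ok <- !is.na(m)
    sum(response_parities[ok] == digit_parities[m[ok]])
  }, numeric(1))
  max(matches) / max(n_d, n_r)
}

#' Rating accuracy as a Spearman correlation
#'
#' Correlates the 1-4 ratings with the true values (closeness in density for
#' memory trials; actual density for non-memory trials) using Spearman's rank
#' correlation with average ranks for ties. Missing responses are replaced by
#' 2.5, the midpoint of both rating scales.
#'
#' @param responses Ratings 1-4, `NA` for missing.
#' @param true_values True quantity per trial (same length).
#' @return Spearman's rho, or `NA` when fewer than 3 trials are available or a
#'   series has zero variance (e.g. all responses missing).
#' @export
rating_accuracy <- function(responses, true_values) {
  if (length(responses) != length(true_values)) {
    stop("responses and true_values must have equal length", call. = FALSE)
  }
  if (length(responses) < 3L) return(NA_real_)
  responses[is.na(responses)] <- 2.5
  if (stats::sd(responses) == 0 || stats::sd(true_values) == 0) {
    return(NA_real_)
  }
  suppressWarnings(stats::cor(responses, true_values, method = "spearman"))
}

#' Variance-stabilizing transforms for group statistics
#'
#' Proportions are compared after the arcsine square-root transform and
#' correlation coefficients after the Fisher z-transform.
#'
#' @param p Proportions in \[0, 1\].
#' @param r Correlations in (-1, 1).
#' @return Transformed values.
#' @export
transform_proportion <- function(p) {
  if (any(p < 0 | p > 1)) stop("proportions must lie in [0, 1]", call. = FALSE)
  asin(sqrt(p))
}

#' @rdname transform_proportion
#' @export
transform_correlation <- function(r) {
  if (any(abs(r) >= 1)) stop("correlations must lie strictly in (-1, 1)",
                             call. = FALSE)
  atanh(r)
}

#' Participant exclusion flags
#'
#' Flags subjects performing more than two standard deviations below the group
#' mean on the adjustment task (performance = negative mean final distance to
#' target, so lower distance is better) and subjects whose maximum head
#' displacement exceeds 3 mm (one voxel). With zero between-subject variance
#' no performance flags are raised.
#'
#' @param adjust_mean_distance Per-subject mean final distance (levels).
#' @param motion_max_mm Per-subject maximum displacement (mm).
#' @param motion_limit_mm Displacement threshold (default 3).
#' @return Data frame: `low_performance`, `high_motion`, `exclude`.
#' @export
exclusion_flags <- function(adjust_mean_distance, motion_max_mm,
                            motion_limit_mm = 3) {
  n <- length(adjust_mean_distance)
  if (n < 3L) stop("need >= 3 subjects for the SD rule", call. = FALSE)
  if (length(motion_max_mm) != n) {
    stop("score and motion vectors must have equal length", call. = FALSE)
  }
  perf <- -adjust_mean_distance
  s <- stats::sd(perf)
  low <- if (s == 0) rep(FALSE, n) else perf < mean(perf) - 2 * s
  mover <- motion_max_mm > motion_limit_mm
  data.frame(low_performance = low, high_motion = mover,
             exclude = low | mover)
}
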
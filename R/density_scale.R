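#' Construct a logarithmically spaced tone-count density scale
#'
#' The density dimension is the number of concurrent pure tones in a 190-ms
#' stack. Levels are placed on a geometric (log-spaced) grid between
#' `min_tones` and `max_tones` and rounded to integers, because perceptual
#' discriminability of density is approximately constant on a log scale.
#' Rounding at the sparse end can collide (e.g. the second point of the
#' 2..196 grid, 2 * 98^(1/25) = 2.40, rounds to 2); collisions are resolved
#' by incrementing to the next unused integer upward, which preserves strict
#' monotonicity and the exact endpoints.
#'
#' @param min_tones Smallest tone count (default 2).
#' @param max_tones Largest tone count (default 196).
#' @param n_levels Number of levels (default 26).
#' @return An object of class `density_scale`: a list with `levels`
#'   (strictly increasing integer tone counts), `n_levels`, `min_tones`,
#'   `max_tones`.
#' @examples
#' sc <- make_density_scale()
#' sc$levels[c(1, 26)]  # 2 and 196
#' @export
make_density_scale <- function(min_tones = 2L, max_tones = 196L, n_levels = 26L) {
  stopifnot_scalar_number(min_tones, "min_tones")
  stopifnot_scalar_number(max_tones, "max_tones")
  stopifnot_scalar_number(n_levels, "n_levels")
  min_tones <- as.integer(min_tones); max_tones <- as.integer(max_tones)
  n_levels <- as.integer(n_levels)
  if (min_tones < 1L || min_tones >= max_tones) {
    stop("need 1 <= min_tones < max_tones", call. = FALSE)
  }
  if (n_levels < 2L) stop("n_levels must be >= 2", call. = FALSE)
  if (n_levels > max_tones - min_tones + 1L) {
    stop("n_levels exceeds the number of distinct integers in [min_tones, max_tones]",
         call. = FALSE)
  }
  grid <- exp(seq(log(min_tones), log(max_tones), length.out = n_levels))
  levels <- as.integer(round(grid))
  # resolve duplicate rounded counts upward to the next unused integer
  for (i in seq_along(levels)[-1]) {
    if (levels[i] <= levels[i - 1L]) levels[i] <- levels[i - 1L] + 1L
  }
  if (levels[n_levels] > max_tones) {
    stop("could not place strictly increasing levels within [min_tones, max_tones]",
         call. = FALSE)
  }
  levels[1L] <- min_tones
  levels[n_levels] <- max_tones
  structure(
    list(levels = levels, n_levels = n_levels,
         min_tones = min_tones, max_tones = max_tones),
    class = "density_scale"
  )
}

#' @export
print.density_scale <- function(x, ...) {
  cat(sprintf("<density_scale> %d levels, %d..%d tones\n",
              x$n_levels, x$min_tones, x$max_tones))
  cat(" levels:", paste(x$levels, collapse = " "), "\n")
  invisible(x)
}

#' Median level split used for binary density labels
#'
#' Splits the ordered levels into a lower and an upper group of (near-)equal
#' size; for a 26-level scale levels 1-13 are "low" and 14-26 "high".
#'
#' @param scale A `density_scale`.
#' @param level_index Integer level indices.
#' @return Character vector, `"low"` or `"high"` per index.
#' @export
density_split <- function(scale, level_index) {
  stopifnot(inherits(scale, "density_scale"))
  if (any(level_index < 1L | level_index > scale$n_levels)) {
    stop("level index out of range", call. = FALSE)
  }
  ifelse(level_index <= scale$n_levels %/% 2L, "low", "high")
}
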
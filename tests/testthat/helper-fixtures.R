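# Shared fixtures, built in code at test time.

test_scale <- function() make_density_scale(2, 196, 26)

# one small yoked run with simulated behavior, cached per test file
test_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_session(test_scale(), n_runs = 1, seed = 402)
    }
    cache
  }
})

# tiny grid for neuroimaging tests
test_geom <- function(shape = c(10, 10, 8)) {
  make_grid_and_rois(shape = shape,
                     roi_voxels = c(auditory = 20L, hippocampus = 20L))
}

# independent exhaustive oracle for the dislocation-tolerant parity score:
# equal counts -> positional; one extra response -> best single drop;
# one missing response -> best single gap insertion.
oracle_parity <- function(digits, resps) {
  n_d <- length(digits); n_r <- length(resps)
  if (n_r == 0 || n_d == 0) return(0)
  pos_matches <- function(d, r) {
    n <- min(length(d), length(r))
    if (n == 0) return(0)
    sum(d[seq_len(n)] == r[seq_len(n)], na.rm = TRUE)
  }
  best <- 0
  if (n_r > n_d) {
    for (k in seq_len(n_r)) {
      best <- max(best, pos_matches(digits, resps[-k]))
    }
  } else if (n_r < n_d) {
    for (k in seq_len(n_d)) {
      padded <- append(resps, NA, after = k - 1)
      best <- max(best, pos_matches(digits, padded))
    }
  } else {
    best <- pos_matches(digits, resps)
  }
  best / max(n_d, n_r)
}
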
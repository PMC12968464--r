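#' Draw tone frequencies from a log-uniform distribution
#'
#' Frequencies are i.i.d. log-uniform on `[f_lo, f_hi]` (uniform in
#' log-frequency), the standard choice for tone clouds so that octaves are
#' sampled evenly.
#'
#' @param n_tones Number of frequencies (>= 1).
#' @param f_lo,f_hi Band edges in Hz (defaults 250 and 4000).
#' @param seed Optional integer seed for a reproducible draw.
#' @return Numeric vector of `n_tones` frequencies in Hz.
#' @export
sample_frequencies <- function(n_tones, f_lo = 250, f_hi = 4000, seed = NULL) {
  stopifnot_scalar_number(n_tones, "n_tones")
  if (n_tones < 1) stop("n_tones must be >= 1", call. = FALSE)
  if (!is.numeric(f_lo) || !is.numeric(f_hi) || f_lo <= 0 || f_hi <= f_lo) {
    stop("need 0 < f_lo < f_hi", call. = FALSE)
  }
  with_seed(seed, exp(stats::runif(n_tones, log(f_lo), log(f_hi))))
}

#' Tone-stack specification
#'
#' A tone stack is a brief chord of simultaneous pure tones with raised-cosine
#' onset/offset ramps, followed in a series by a short silent gap. Defaults
#' follow the experiment: 190 ms stacks, 2 ms ramps, 10 ms gaps.
#'
#' @param n_tones Number of concurrent tones (>= 1).
#' @param frequencies Vector of `n_tones` frequencies in Hz within [250, 4000]
#'   unless `f_range` overrides.
#' @param duration_s Stack duration in seconds (default 0.190).
#' @param ramp_s Raised-cosine ramp duration in seconds (default 0.002).
#' @param gap_s Following silence in seconds (default 0.010).
#' @param rms_target Target linear RMS amplitude (default 0.05).
#' @param f_range Allowed frequency range (default `c(250, 4000)`).
#' @return An object of class `tone_stack`.
#' @export
tone_stack <- function(n_tones, frequencies,
                       duration_s = 0.190, ramp_s = 0.002, gap_s = 0.010,
                       rms_target = 0.05, f_range = c(250, 4000)) {
  n_tones <- as.integer(n_tones)
  if (n_tones < 1L) stop("n_tones must be >= 1", call. = FALSE)
  if (length(frequencies) != n_tones) {
    stop("length(frequencies) must equal n_tones", call. = FALSE)
  }
  if (any(frequencies < f_range[1] | frequencies > f_range[2])) {
    stop("frequencies outside allowed range", call. = FALSE)
  }
  if (duration_s <= 0 || ramp_s <= 0 || gap_s <= 0) {
    stop("duration, ramp and gap must be strictly positive", call. = FALSE)
  }
  if (2 * ramp_s >= duration_s) stop("ramps exceed stack duration", call. = FALSE)
  structure(
    list(n_tones = n_tones, frequencies = as.numeric(frequencies),
         duration_s = duration_s, ramp_s = ramp_s, gap_s = gap_s,
         rms_target = rms_target),
    class = "tone_stack"
  )
}

new_waveform <- function(samples, sample_rate_hz) {
  structure(list(samples = samples, sample_rate_hz = as.integer(sample_rate_hz)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %.3f s @ %d Hz (peak %.3f, rms %.4f)\n",
              length(x$samples) / x$sample_rate_hz, x$sample_rate_hz,
              max(abs(x$samples)), sqrt(mean(x$samples^2))))
  invisible(x)
}

#' Synthesize a single tone stack
#'
#' Sums equal-amplitude sinusoids with random phases (uniform on \[0, 2*pi)),
#' applies raised-cosine on/offset ramps, and rescales the result so its RMS
#' over the full stack equals `rms_target`. Because the scaling is applied per
#' stack, stacks of any density are equated for RMS intensity by construction.
#'
#' @param stack A [tone_stack()].
#' @param sample_rate_hz Sampling rate (default 44100). Must exceed twice the
#'   highest component frequency.
#' @param seed Optional seed controlling the random phases.
#' @return A `waveform` (samples do not include the trailing gap).
#' @export
synth_stack <- function(stack, sample_rate_hz = 44100L, seed = NULL) {
  stopifnot(inherits(stack, "tone_stack"))
  if (sample_rate_hz <= 2 * max(stack$frequencies)) {
    stop("sample rate below Nyquist for the highest component", call. = FALSE)
  }
  n <- round(stack$duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  phases <- with_seed(seed, stats::runif(stack$n_tones, 0, 2 * pi))
  x <- numeric(n)
  for (k in seq_len(stack$n_tones)) {
    x <- x + sin(2 * pi * stack$frequencies[k] * t + phases[k])
  }
  nr <- round(stack$ramp_s * sample_rate_hz)
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
    x[seq_len(nr)] <- x[seq_len(nr)] * ramp
    x[n - nr + seq_len(nr)] <- x[n - nr + seq_len(nr)] * rev(ramp)
  }
  x <- x * stack$rms_target / sqrt(mean(x^2))
  new_waveform(x, sample_rate_hz)
}

#' Synthesize a series of tone stacks
#'
#' Concatenates one stack per requested density level, each followed by the
#' 10-ms gap, with a fresh random draw of component frequencies for every
#' stack regardless of whether the density changes. Ten stacks give the 2-s
#' initial sound; forty give the 8-s adjustment-phase stream.
#'
#' @param level_indices Integer level indices into `scale`.
#' @param scale A [make_density_scale()] object.
#' @param sample_rate_hz Sampling rate (default 44100).
#' @param rms_target Per-stack RMS target (default 0.05).
#' @param seed Optional seed; fixes frequencies and phases for the whole series.
#' @return A `waveform` of duration `0.200 * length(level_indices)` seconds.
#' @export
synth_series <- function(level_indices, scale, sample_rate_hz = 44100L,
                         rms_target = 0.05, seed = NULL) {
  stopifnot(inherits(scale, "density_scale"))
  if (length(level_indices) == 0) stop("empty level series", call. = FALSE)
  if (any(level_indices < 1L | level_indices > scale$n_levels)) {
    stop("level index out of range", call. = FALSE)
  }
  with_seed(seed, {
    gap_n <- round(0.010 * sample_rate_hz)
    pieces <- lapply(level_indices, function(idx) {
      n_tones <- scale$levels[idx]
      st <- tone_stack(n_tones, sample_frequencies(n_tones),
                       rms_target = rms_target)
      c(synth_stack(st, sample_rate_hz)$samples, numeric(gap_n))
    })
    new_waveform(unlist(pieces), sample_rate_hz)
  })
}

#' Write a waveform to a PCM WAV file
#'
#' Minimal RIFF/WAVE writer supporting 16-bit integer and 32-bit IEEE float
#' mono PCM. Samples with magnitude above 0.999 are rescaled to peak 0.9 with
#' a warning (RMS targeting normally keeps peaks well below full scale).
#'
#' @param wave A `waveform`.
#' @param path Output file path.
#' @param bits 16 (integer PCM) or 32 (float PCM).
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, bits = 16L) {
  stopifnot(inherits(wave, "waveform"))
  if (!bits %in% c(16L, 32L)) stop("bits must be 16 or 32", call. = FALSE)
  x <- wave$samples
  if (max(abs(x)) > 0.999) {
    warning("waveform peak exceeds full scale; rescaling to peak 0.9")
    x <- x * 0.9 / max(abs(x))
  }
  sr <- wave$sample_rate_hz
  bytes_per <- bits %/% 8L
  data_n <- length(x) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  fmt <- if (bits == 16L) 1L else 3L  # PCM vs IEEE float
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_n), con, size = 4, endian = "little")
  if (bits == 16L) {
    writeBin(as.integer(round(pmax(-1, pmin(1, x)) * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a PCM WAV file written by [write_wav()]
#'
#' @param path WAV file path.
#' @return A `waveform`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4); readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") stop("not a RIFF/WAVE file", call. = FALSE)
  fmt_tag <- sr <- bits <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_tag <- readBin(con, "integer", size = 2, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      sr <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (sz > 16) readBin(con, "raw", n = sz - 16)
    } else if (id == "data") {
      if (bits == 16L) {
        samples <- readBin(con, "integer", n = sz %/% 2L, size = 2,
                           endian = "little") / 32767
      } else {
        samples <- readBin(con, "numeric", n = sz %/% 4L, size = 4,
                           endian = "little")
      }
      break
    } else {
      readBin(con, "raw", n = sz)
    }
  }
  if (is.null(samples)) stop("no data chunk found", call. = FALSE)
  new_waveform(samples, sr)
}
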
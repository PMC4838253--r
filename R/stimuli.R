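#' Stimulus specification for a ramped or damped sinusoid train
#'
#' A ramped/damped sinusoid is a pure-tone carrier multiplied by a periodic
#' exponential envelope that either decays within each cycle (damped) or is its
#' within-cycle time mirror (ramped).  The two members of a pair share the same
#' long-term magnitude spectrum but differ strongly in perceived tonal
#' salience.
#'
#' The cycle length must contain an integer number of carrier periods so that
#' the envelope discontinuity at every cycle boundary falls on an upward-going
#' zero crossing of the carrier and all cycles start in the same phase.
#'
#' @param carrier_hz Carrier frequency in Hz.
#' @param half_life_ms Envelope half-life T1/2 in ms.
#' @param envelope_type `"ramped"` or `"damped"`.
#' @param n_cycles Number of concatenated modulation cycles.
#' @param cycle_ms Cycle length in ms.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param level_ref Dimensionless normalization constant used by
#'   [normalize_level()]; `NULL` selects the package default (see
#'   [reference_level()]).
#' @return An object of class `"stimulus_spec"`.
#' @seealso [synthesize_train()], [envelope()]
#' @export
stimulus_spec <- function(carrier_hz = 1000, half_life_ms = 4,
                          envelope_type = c("ramped", "damped"),
                          n_cycles = 20, cycle_ms = 50,
                          sample_rate_hz = 48000, level_ref = NULL) {
  envelope_type <- match.arg(envelope_type)
  if (carrier_hz <= 0) stop("carrier_hz must be positive")
  if (half_life_ms <= 0) stop("half_life_ms must be positive")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  periods <- cycle_ms * carrier_hz / 1000
  if (abs(periods - round(periods)) > 1e-9) {
    stop("cycle_ms must contain an integer number of carrier periods; ",
         "phase alignment at cycle boundaries is impossible otherwise")
  }
  structure(list(carrier_hz = carrier_hz, half_life_ms = half_life_ms,
                 envelope_type = envelope_type, n_cycles = n_cycles,
                 cycle_ms = cycle_ms, sample_rate_hz = sample_rate_hz,
                 level_ref = level_ref),
            class = "stimulus_spec")
}

#' Exponential cycle envelope
#'
#' The damped envelope is `E(t) = (1/T) * exp(-t * log(2) / T)` with `T` the
#' half-life in ms, so the value halves every `T` ms and the peak value is
#' `1/T` per ms.  The ramped envelope is the within-cycle time reverse,
#' `E(cycle_ms - t)`, rising towards the end of the cycle and dropping
#' discontinuously at the boundary.
#'
#' @param t Time within the cycle, ms; must satisfy `0 <= t < cycle_ms`.
#' @param half_life_ms Envelope half-life in ms (> 0).
#' @param envelope_type `"ramped"` or `"damped"`.
#' @param cycle_ms Cycle length in ms.
#' @return Envelope amplitude (units 1/ms), vectorized over `t`.
#' @export
envelope <- function(t, half_life_ms, envelope_type = c("damped", "ramped"),
                     cycle_ms = 50) {
  envelope_type <- match.arg(envelope_type)
  if (half_life_ms <= 0) stop("half_life_ms must be positive")
  if (any(t < 0 | t >= cycle_ms)) {
    stop("t must lie in [0, cycle_ms)")
  }
  u <- if (envelope_type == "damped") t else cycle_ms - t
  (1 / half_life_ms) * exp(-u * log(2) / half_life_ms)
}

#' Synthesize a ramped or damped sinusoid train
#'
#' Multiplies a sine carrier by the periodic exponential envelope of the spec
#' and concatenates `n_cycles` cycles.  The carrier is evaluated at sample
#' instants `i / fs`, so with an integer number of carrier periods per cycle
#' every cycle boundary falls exactly on an upward-going zero crossing.  The
#' envelope is evaluated at sample centers `(i + 1/2) / fs`, which makes the
#' sampled ramped envelope the exact elementwise reverse of the sampled damped
#' envelope within each cycle.
#'
#' @param spec A [stimulus_spec()].
#' @return An object of class `"waveform"`: list with `samples`,
#'   `sample_rate_hz` and `spec`.
#' @export
synthesize_train <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  fs <- spec$sample_rate_hz
  n_per_cycle <- round(spec$cycle_ms * fs / 1000)
  n <- spec$n_cycles * n_per_cycle
  i <- seq_len(n) - 1L
  t_ms <- i * 1000 / fs
  carrier <- sin(2 * pi * spec$carrier_hz * t_ms / 1000)
  u_ms <- ((i %% n_per_cycle) + 0.5) * 1000 / fs
  env <- envelope(u_ms, spec$half_life_ms, spec$envelope_type, spec$cycle_ms)
  structure(list(samples = carrier * env, sample_rate_hz = fs, spec = spec),
            class = "waveform")
}

#' Construct a waveform object from raw samples
#'
#' @param samples Numeric vector of amplitudes.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param spec Optional [stimulus_spec()].
#' @return A `"waveform"` object.
#' @export
waveform <- function(samples, sample_rate_hz, spec = NULL) {
  if (!all(is.finite(samples))) stop("samples must be finite")
  structure(list(samples = as.numeric(samples), sample_rate_hz = sample_rate_hz,
                 spec = spec), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  dur <- length(x$samples) / x$sample_rate_hz
  cat(sprintf("<waveform: %d samples, %.4g s at %g Hz>\n",
              length(x$samples), dur, x$sample_rate_hz))
  if (!is.null(x$spec)) {
    cat(sprintf("  %s, T1/2 = %g ms, carrier %g Hz\n", x$spec$envelope_type,
                x$spec$half_life_ms, x$spec$carrier_hz))
  }
  invisible(x)
}

#' Default level-normalization constant
#'
#' The per-condition level scaling is proportional to the square root of the
#' envelope half-life, which approximately equalizes RMS across half-lives.
#' The proportionality constant is fixed so that the 4 ms damped train at the
#' given geometry has RMS 0.1 full scale after normalization (absolute
#' presentation level is playback-hardware bound and not modelled).
#'
#' @param carrier_hz,n_cycles,cycle_ms,sample_rate_hz Stimulus geometry.
#' @return The scalar `level_ref`.
#' @export
reference_level <- function(carrier_hz = 1000, n_cycles = 20, cycle_ms = 50,
                            sample_rate_hz = 48000) {
  ref <- synthesize_train(stimulus_spec(carrier_hz, 4, "damped", n_cycles,
                                        cycle_ms, sample_rate_hz))
  rms <- sqrt(mean(ref$samples^2))
  0.1 / (rms * sqrt(4))
}

#' Normalize stimulus level by the square root of the half-life
#'
#' Scales the samples by `level_ref * sqrt(half_life_ms)`.  Because the
#' unscaled envelope has peak `1/T` and energy roughly proportional to `1/T`,
#' this brings all half-lives to approximately equal RMS (small deviations
#' remain for the longest half-lives, whose envelopes are truncated by the
#' cycle).
#'
#' @param w A `"waveform"`.
#' @param half_life_ms Envelope half-life in ms; defaults to the spec's value.
#' @param level_ref Normalization constant; defaults to the spec's, else
#'   [reference_level()] at the waveform's geometry.
#' @return A new `"waveform"` with scaled samples.
#' @export
normalize_level <- function(w, half_life_ms = NULL, level_ref = NULL) {
  stopifnot(inherits(w, "waveform"))
  if (is.null(half_life_ms)) half_life_ms <- w$spec$half_life_ms
  if (half_life_ms <= 0) stop("half_life_ms must be positive")
  if (is.null(level_ref)) level_ref <- w$spec$level_ref
  if (is.null(level_ref)) {
    level_ref <- reference_level(w$spec$carrier_hz, w$spec$n_cycles,
                                 w$spec$cycle_ms, w$sample_rate_hz)
  }
  out <- w
  out$samples <- w$samples * level_ref * sqrt(half_life_ms)
  out
}

#' Temporal asymmetry index
#'
#' `AI = (x_ramped - x_damped) / (x_ramped + x_damped)`, a bounded contrast
#' between the values of a measure for the ramped and the damped member of a
#' stimulus pair.  The index is undefined when the denominator is zero and
#' unstable for values near zero, so inference should be run on the raw
#' quantities rather than on the index.
#'
#' @param x_ramped,x_damped Magnitudes for the ramped and damped condition.
#' @return The dimensionless index, in `[-1, 1]` for non-negative inputs.
#' @export
asymmetry_index <- function(x_ramped, x_damped) {
  s <- x_ramped + x_damped
  if (any(s == 0)) stop("asymmetry index undefined: x_ramped + x_damped == 0")
  (x_ramped - x_damped) / s
}

#' The ten experimental stimulus conditions
#'
#' Crossing of envelope type (ramped, damped) with envelope half-life
#' (0.5, 1, 4, 16, 32 ms) at a 1000 Hz carrier, 20 cycles of 50 ms.
#'
#' @param half_lives_ms Half-life values in ms.
#' @param sample_rate_hz Sampling rate in Hz.
#' @return A data frame with columns `condition`, `envelope_type`,
#'   `half_life_ms`.
#' @export
stimulus_conditions <- function(half_lives_ms = c(0.5, 1, 4, 16, 32),
                                sample_rate_hz = 48000) {
  g <- expand.grid(envelope_type = c("ramped", "damped"),
                   half_life_ms = half_lives_ms,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$condition <- condition_id(g$envelope_type, g$half_life_ms)
  g$sample_rate_hz <- sample_rate_hz
  g[, c("condition", "envelope_type", "half_life_ms", "sample_rate_hz")]
}

#' Condition identifier string
#'
#' @param envelope_type `"ramped"` or `"damped"` (vectorized).
#' @param half_life_ms Half-life in ms (vectorized).
#' @return Character vector like `"ramped_4"`.
#' @export
condition_id <- function(envelope_type, half_life_ms) {
  sprintf("%s_%g", envelope_type, half_life_ms)
}

#' Synthesize one experimental condition at normalized level
#'
#' Convenience wrapper: build the spec, synthesize and level-normalize.
#'
#' @param envelope_type `"ramped"` or `"damped"`.
#' @param half_life_ms Half-life in ms.
#' @inheritParams stimulus_spec
#' @return A level-normalized `"waveform"`.
#' @export
synthesize_condition <- function(envelope_type, half_life_ms,
                                 n_cycles = 20, cycle_ms = 50,
                                 carrier_hz = 1000, sample_rate_hz = 48000,
                                 level_ref = NULL) {
  spec <- stimulus_spec(carrier_hz, half_life_ms, envelope_type, n_cycles,
                        cycle_ms, sample_rate_hz, level_ref)
  normalize_level(synthesize_train(spec))
}

#' Write a waveform to a 16-bit PCM WAV file
#'
#' Minimal single-channel RIFF/WAVE writer.  Samples are clipped to
#' `[-1, 1]` and scaled to 16-bit integers.
#'
#' @param w A `"waveform"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  x <- pmax(pmin(w$samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  fs <- as.integer(round(w$sample_rate_hz))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(2L * fs, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
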
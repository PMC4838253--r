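#' Strobe detection with an adaptive, temporally asymmetric threshold
#'
#' In each NAP channel, a strobe is issued at a local maximum of the spike
#' probability that exceeds the current threshold.  On a strobe the threshold
#' is set to the strobed value and then decays linearly to zero over
#' `horizon_ms`.  Rising envelopes (ramped sounds) keep producing maxima above
#' the decaying threshold and therefore yield many strobes per cycle; decaying
#' envelopes fall below the threshold set by their onset peak and yield few.
#' A noise floor (`min_frac` of the channel's maximum activity) keeps
#' near-zero ripples during silent stretches, where the adaptive threshold
#' has fully decayed, from issuing spurious strobes.
#'
#' @param nap A `"nap"`.
#' @param horizon_ms Linear-decay horizon of the threshold in ms.
#' @param min_frac Strobe floor as a fraction of the channel's maximum
#'   activity.
#' @return An object of class `"strobe_train"`: list with `times_ms`
#'   (per-channel list of strobe times, strictly increasing), `values`
#'   (strobed NAP values), `sample_rate_hz`, `horizon_ms`.
#' @export
detect_strobes <- function(nap, horizon_ms = 20, min_frac = 0.05) {
  stopifnot(inherits(nap, "nap"))
  fs <- nap$sample_rate_hz
  dt <- 1000 / fs
  n <- nrow(nap$p)
  times <- vector("list", ncol(nap$p))
  values <- vector("list", ncol(nap$p))
  for (k in seq_len(ncol(nap$p))) {
    x <- nap$p[, k]
    if (n < 3) {
      times[[k]] <- numeric(0)
      values[[k]] <- numeric(0)
      next
    }
    i <- 2:(n - 1)
    floor_k <- min_frac * max(x)
    cand <- i[x[i] > 0 & x[i] >= floor_k & x[i] >= x[i - 1] & x[i] > x[i + 1]]
    st <- numeric(0)
    sv <- numeric(0)
    last_t <- -Inf
    last_v <- 0
    for (idx in cand) {
      t_ms <- (idx - 1) * dt
      thr <- last_v * max(0, 1 - (t_ms - last_t) / horizon_ms)
      if (x[idx] > thr) {
        st <- c(st, t_ms)
        sv <- c(sv, x[idx])
        last_t <- t_ms
        last_v <- x[idx]
      }
    }
    times[[k]] <- st
    values[[k]] <- sv
  }
  structure(list(times_ms = times, values = values, sample_rate_hz = fs,
                 horizon_ms = horizon_ms),
            class = "strobe_train")
}

#' @export
print.strobe_train <- function(x, ...) {
  counts <- lengths(x$times_ms)
  cat(sprintf("<strobe_train: %d channels, %d strobes total (%.1f/channel)>\n",
              length(counts), sum(counts), mean(counts)))
  invisible(x)
}

#' Build the stabilised auditory image
#'
#' On each strobe, the NAP segment following the strobe point is copied into
#' that channel's time-interval buffer, aligned at interval zero; between
#' strobes the buffer decays exponentially with time constant `decay_ms`
#' (default 30 ms), which lets the image respond to rapid stimulus changes.
#' By default the image is this raw decaying accumulation: a channel that
#' strobes often within the decay window builds a taller image, which is how
#' the multiple snapshots taken on a rising envelope amplify the
#' ramped/damped contrast beyond the auditory-nerve level.  With
#' `normalize = TRUE` each snapshot is instead weighted by its strobed
#' activity value and the channel buffer is divided by its (equally decayed)
#' cumulative strobe weight, yielding an activity-weighted average image
#' whose ridge heights are independent of strobe rate; the summary is then
#' weighted across channels by strobe weight.  The averaged form is useful
#' for inspecting snapshot shape, but it removes the accumulation advantage
#' of dense strobing and with it the perceptual asymmetry, so the
#' accumulating image is the salience read-out.
#'
#' The interval axis is reported with a negative sign (delays into the past),
#' following the usual display convention; magnitudes are used for all
#' computations.
#'
#' @param nap The `"nap"` the strobes were derived from.
#' @param strobes A `"strobe_train"` from [detect_strobes()].
#' @param decay_ms Buffer decay time constant in ms.
#' @param interval_ms Interval-axis length in ms.
#' @param normalize Weight snapshots by strobed value and divide by the
#'   decayed cumulative strobe weight (activity-weighted average image)
#'   instead of accumulating.
#' @return An object of class `"sai"`: list with `image` (channel x interval
#'   matrix, final buffer state), `interval_axis_ms` (negative), `summary`
#'   (weighted mean across channels), `channel_weight`, `decay_ms`, `cfs`,
#'   `sample_rate_hz`.
#' @export
build_sai <- function(nap, strobes, decay_ms = 30, interval_ms = 35,
                      normalize = FALSE) {
  stopifnot(inherits(nap, "nap"), inherits(strobes, "strobe_train"))
  if (decay_ms <= 0) stop("decay_ms must be positive")
  if (abs(nap$sample_rate_hz - strobes$sample_rate_hz) > 1e-9) {
    stop("strobes were not derived from this NAP")
  }
  fs <- nap$sample_rate_hz
  dt <- 1000 / fs
  n <- nrow(nap$p)
  b <- round(interval_ms * fs / 1000)
  nch <- ncol(nap$p)
  end_ms <- (n - 1) * dt
  image <- matrix(0, nch, b)
  ch_weight <- numeric(nch)
  for (k in seq_len(nch)) {
    buf <- numeric(b)
    wgt <- 0
    st <- strobes$times_ms[[k]]
    sv <- strobes$values[[k]]
    prev_ms <- 0
    for (s in seq_along(st)) {
      s_ms <- st[s]
      w_s <- if (normalize) sv[s] else 1
      fade <- exp(-(s_ms - prev_ms) / decay_ms)
      buf <- buf * fade
      wgt <- wgt * fade
      i0 <- round(s_ms / dt) + 1
      seg_len <- min(b, n - i0 + 1)
      seg <- numeric(b)
      seg[seq_len(seg_len)] <- nap$p[i0:(i0 + seg_len - 1), k]
      buf <- buf + w_s * seg
      wgt <- wgt + w_s
      prev_ms <- s_ms
    }
    fade <- exp(-(end_ms - prev_ms) / decay_ms)
    buf <- buf * fade
    wgt <- wgt * fade
    ch_weight[k] <- wgt
    if (normalize && wgt > 0) buf <- buf / wgt
    image[k, ] <- buf
  }
  summary <- if (normalize && sum(ch_weight) > 0) {
    colSums(image * ch_weight) / sum(ch_weight)
  } else {
    colMeans(image)
  }
  structure(list(image = image,
                 interval_axis_ms = -(seq_len(b) - 1) * dt,
                 summary = summary, channel_weight = ch_weight,
                 decay_ms = decay_ms,
                 cfs = nap$cfs, sample_rate_hz = fs),
            class = "sai")
}

#' @export
print.sai <- function(x, ...) {
  cat(sprintf("<sai: %d channels x %d intervals (0..%.1f ms), decay %g ms>\n",
              nrow(x$image), ncol(x$image), -min(x$interval_axis_ms),
              x$decay_ms))
  invisible(x)
}

#' Signed interval position of the summary-image peak
#'
#' The highest interior local maximum of the summary curve over interval
#' magnitude; the interval-zero bin (where every strobed segment starts at its
#' own strobe value) and its monotone shoulder are excluded, as in the usual
#' "first peak" read-out of the image.  For a tonal stimulus this peak sits at
#' the carrier period.
#'
#' @param sai An `"sai"`.
#' @return Signed interval in ms (negative), or `NA` if the image is empty.
#' @export
sai_peak_interval <- function(sai) {
  stopifnot(inherits(sai, "sai"))
  mag <- -sai$interval_axis_ms
  pk <- pick_peak_lag(sai$summary, mag)
  if (is.na(pk)) NA_real_ else -pk
}

#' Carrier-ridge salience of a stabilised auditory image
#'
#' Height of the summary-image peak nearest the carrier period.  The height of
#' this first ridge predicts the perceived salience of the carrier pitch.
#'
#' @param sai An `"sai"`.
#' @param carrier_hz Carrier frequency in Hz.
#' @param tol_frac Search tolerance around the carrier period, as a fraction
#'   of the period.
#' @return Peak height (activity units); 0 for an all-zero image.
#' @export
carrier_salience <- function(sai, carrier_hz = 1000, tol_frac = 0.5) {
  stopifnot(inherits(sai, "sai"))
  if (all(sai$summary == 0)) return(0)
  period <- 1000 / carrier_hz
  mag <- -sai$interval_axis_ms
  if (max(mag) < period) stop("interval axis does not cover the carrier period")
  v <- sai$summary
  n <- length(v)
  i <- 2:(n - 1)
  is_peak <- v[i] >= v[i - 1] & v[i] >= v[i + 1] &
    (v[i] > v[i - 1] | v[i] > v[i + 1]) & v[i] > 0
  cand <- i[is_peak]
  cand <- cand[abs(mag[cand] - period) <= tol_frac * period]
  if (length(cand) == 0) stop("no local peak near the carrier interval")
  max(v[cand])
}

#' NAP-level energy measure
#'
#' Mean spike probability over time and channels: a baseline measure of
#' peripheral drive, used to show how much the strobed integration amplifies
#' ramped/damped differences relative to the auditory-nerve level.
#'
#' @param nap A `"nap"`.
#' @return Scalar mean activity.
#' @export
nap_energy <- function(nap) {
  stopifnot(inherits(nap, "nap"))
  mean(nap$p)
}
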
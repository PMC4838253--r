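#' Source waveform of an auditory evoked field
#'
#' A single-dipole source time course for one subject, hemisphere and
#' stimulus condition, sampled at 1 kHz over an epoch from -500 ms to
#' 1400 ms relative to tone onset (units are nAm-like source amplitudes).
#'
#' @param samples Numeric vector of source amplitudes.
#' @param sample_rate_hz Sampling rate (default 1000).
#' @param t_start_ms Epoch start relative to onset (default -500).
#' @param subject,hemisphere,condition Optional identifiers; `hemisphere` is
#'   `"left"`, `"right"` or `"avg"`.
#' @return An object of class `"source_waveform"`.
#' @export
source_waveform <- function(samples, sample_rate_hz = 1000,
                            t_start_ms = -500, subject = NA,
                            hemisphere = NA, condition = NA) {
  if (!all(is.finite(samples))) stop("samples must be finite")
  w <- structure(list(samples = as.numeric(samples),
                      sample_rate_hz = sample_rate_hz,
                      t_start_ms = t_start_ms, subject = subject,
                      hemisphere = hemisphere, condition = condition),
                 class = "source_waveform")
  t <- sw_time(w)
  if (min(t) > -100 || max(t) < 1000) {
    stop("epoch must cover at least -100..1000 ms")
  }
  w
}

#' Time axis of a source waveform
#'
#' @param w A `"source_waveform"`.
#' @return Vector of times in ms relative to onset.
#' @export
sw_time <- function(w) {
  w$t_start_ms + (seq_along(w$samples) - 1) * 1000 / w$sample_rate_hz
}

#' Baseline and drift correction of an epoch
#'
#' Subtracts the mean of the 100 ms interval before tone onset, then removes
#' the dominant trend of the final 100 ms of the epoch: a linear
#' offset-plus-slope component is estimated over that segment (its first
#' principal direction for a single time series) and extrapolated across the
#' whole epoch.  The baseline is re-zeroed afterwards so both corrections
#' hold simultaneously.
#'
#' @param w A `"source_waveform"`.
#' @return The corrected `"source_waveform"`.
#' @export
preprocess_epoch <- function(w) {
  stopifnot(inherits(w, "source_waveform"))
  t <- sw_time(w)
  x <- w$samples
  base <- t >= -100 & t < 0
  if (!any(base)) stop("epoch does not cover the baseline interval")
  x <- x - mean(x[base])
  tail_start <- max(t) - 100
  tail <- t >= tail_start
  if (sum(tail) < 10) stop("epoch too short for drift estimation")
  fit <- stats::lm.fit(cbind(1, t[tail]), x[tail])
  x <- x - (fit$coefficients[1] + fit$coefficients[2] * t)
  x <- x - mean(x[base])
  out <- w
  out$samples <- x
  out
}

#' Average the two hemispheres of a subject
#'
#' @param wl,wr `"source_waveform"`s for the left and right hemisphere of the
#'   same subject and condition.
#' @return A `"source_waveform"` with `hemisphere = "avg"`.
#' @export
average_hemispheres <- function(wl, wr) {
  stopifnot(length(wl$samples) == length(wr$samples),
            wl$t_start_ms == wr$t_start_ms)
  out <- wl
  out$samples <- (wl$samples + wr$samples) / 2
  out$hemisphere <- "avg"
  out
}

#' Measure the N100m deflection
#'
#' The N100m is the negative-going transient about 100 ms after onset: the
#' amplitude is the minimum value inside the search window (signed), the
#' latency its time; ties go to the earliest sample.  If the minimum sits on
#' the window boundary the waveform is monotone there and the measurement is
#' flagged.
#'
#' @param w A preprocessed `"source_waveform"`.
#' @param search_window Length-2 window in ms post-onset.
#' @return List with `amplitude` (signed), `magnitude` (`abs(amplitude)`),
#'   `latency_ms`, `flagged`.
#' @export
measure_n100m <- function(w, search_window = c(50, 200)) {
  stopifnot(inherits(w, "source_waveform"))
  t <- sw_time(w)
  sel <- which(t >= search_window[1] & t <= search_window[2])
  if (length(sel) < 3) stop("search window not covered by the epoch")
  x <- w$samples[sel]
  i <- which.min(x)
  flagged <- (i == 1 || i == length(sel)) || all(x == x[1])
  list(amplitude = x[i], magnitude = abs(x[i]), latency_ms = t[sel[i]],
       flagged = flagged)
}

#' Measure the sustained-field depth
#'
#' Mean amplitude over the late DC-like portion of the epoch (800-1000 ms
#' inclusive by default; 201 samples at 1 kHz).
#'
#' @param w A preprocessed `"source_waveform"`.
#' @param window Length-2 window in ms post-onset.
#' @return List with `depth` (signed mean) and `n` (samples used).
#' @export
measure_sf <- function(w, window = c(800, 1000)) {
  stopifnot(inherits(w, "source_waveform"))
  t <- sw_time(w)
  sel <- t >= window[1] & t <= window[2]
  if (!any(t <= window[1]) || !any(t >= window[2])) {
    stop("epoch does not cover the sustained-field window")
  }
  list(depth = mean(w$samples[sel]), n = sum(sel))
}

#' Pooled per-subject sample for nonparametric testing
#'
#' For `mode = "n100m"`: for each subject the peak sample plus every sample
#' within 15 ms on either side of the peak (31 values at 1 kHz).  For
#' `mode = "sf"`: every sample in the 800-1000 ms window (201 values at
#' 1 kHz).  Values are pooled across subjects, so 27 subjects give n = 837
#' and n = 5427 respectively.
#'
#' @param waves List of preprocessed `"source_waveform"`s, one per subject.
#' @param mode `"n100m"` or `"sf"`.
#' @param halfwidth_ms Pooling half-width around the N100m peak.
#' @param search_window N100m search window, ms.
#' @param sf_window Sustained-field window, ms.
#' @return Numeric vector of pooled values.
#' @export
pooled_sample <- function(waves, mode = c("n100m", "sf"), halfwidth_ms = 15,
                          search_window = c(50, 200),
                          sf_window = c(800, 1000)) {
  mode <- match.arg(mode)
  rates <- vapply(waves, function(w) w$sample_rate_hz, numeric(1))
  if (length(unique(rates)) != 1) stop("inconsistent sampling rates")
  out <- lapply(waves, function(w) {
    t <- sw_time(w)
    if (mode == "n100m") {
      m <- measure_n100m(w, search_window)
      w$samples[t >= m$latency_ms - halfwidth_ms &
                  t <= m$latency_ms + halfwidth_ms]
    } else {
      w$samples[t >= sf_window[1] & t <= sf_window[2]]
    }
  })
  unlist(out, use.names = FALSE)
}

#' Two-sided Wilcoxon rank-sum comparison of two pooled samples
#'
#' @param sample_a,sample_b Numeric vectors.
#' @return List with `statistic` (W) and `p`.
#' @export
compare_conditions <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) stop("empty sample")
  ht <- stats::wilcox.test(sample_a, sample_b, exact = FALSE)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Pearson correlation between per-condition values
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return List with `r` and `p` (two-sided).
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for zero-variance input")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value)
}

#' Fit the linear map from model derivative to evoked amplitude
#'
#' Least-squares fit of `field = slope * deriv + intercept` over a window
#' (default 50 ms) centred on the N100m peak.  The model derivative, sampled
#' on its own time base, is linearly interpolated at the field's sample
#' times.
#'
#' @param deriv_t_ms,deriv Model-derivative time base (ms post-onset) and
#'   values.
#' @param field A preprocessed `"source_waveform"`.
#' @param center_ms Window centre (the N100m latency); default: measured from
#'   `field`.
#' @param window_ms Window length in ms.
#' @return List with `slope`, `intercept`, `r`, `rmse`, `n`, `center_ms`.
#' @export
fit_linear_map <- function(deriv_t_ms, deriv, field, center_ms = NULL,
                           window_ms = 50) {
  stopifnot(inherits(field, "source_waveform"))
  if (is.null(center_ms)) center_ms <- measure_n100m(field)$latency_ms
  t <- sw_time(field)
  sel <- t >= center_ms - window_ms / 2 & t <= center_ms + window_ms / 2
  if (sum(sel) < 3) stop("window outside the field epoch")
  if (min(deriv_t_ms) > center_ms - window_ms / 2 ||
      max(deriv_t_ms) < center_ms + window_ms / 2) {
    stop("window outside the model-derivative series")
  }
  x <- stats::approx(deriv_t_ms, deriv, xout = t[sel])$y
  y <- field$samples[sel]
  if (stats::sd(x) == 0) stop("constant derivative: linear map rank-deficient")
  fit <- stats::lm(y ~ x)
  pred <- stats::fitted(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = if (stats::sd(y) > 0) stats::cor(x, y) else NA_real_,
       rmse = sqrt(mean((y - pred)^2)), n = sum(sel), center_ms = center_ms)
}

#' Leave-one-in cross-validation of the model-to-field map
#'
#' For every condition, the linear map is fitted on each subject in turn and
#' then evaluated on each of the remaining subjects, giving `N (N - 1)` folds
#' per condition (702 for 27 subjects).  Each fold reports the Pearson
#' correlation and root-mean-square error between the predicted and observed
#' field in the window around the N100m peak.
#'
#' @param fields_by_subject List over subjects; each element a named list
#'   over conditions of preprocessed `"source_waveform"`s.
#' @param derivs Named list over conditions: each a list with `time_ms` and
#'   `deriv` (model-derivative series).
#' @param centers Optional named vector of window centres per condition;
#'   default: grand-mean N100m latency per condition.
#' @param window_ms Window length in ms.
#' @return A `"cv_result"`: list with `folds` (data frame: condition,
#'   fit_subject, test_subject, slope, intercept, r, rmse) and
#'   `folds_per_condition`.
#' @export
cross_validate <- function(fields_by_subject, derivs, centers = NULL,
                           window_ms = 50) {
  ns <- length(fields_by_subject)
  if (ns < 2) stop("need at least 2 subjects")
  conds <- names(derivs)
  if (is.null(centers)) {
    centers <- vapply(conds, function(cn) {
      gm <- rowMeans(vapply(fields_by_subject,
                            function(s) s[[cn]]$samples,
                            numeric(length(fields_by_subject[[1]][[cn]]$samples))))
      gw <- fields_by_subject[[1]][[cn]]
      gw$samples <- gm
      measure_n100m(gw)$latency_ms
    }, numeric(1))
  }
  rows <- list()
  for (cn in conds) {
    d <- derivs[[cn]]
    fits <- lapply(fields_by_subject, function(s) {
      fit_linear_map(d$time_ms, d$deriv, s[[cn]], centers[[cn]], window_ms)
    })
    for (i in seq_len(ns)) {
      fi <- fits[[i]]
      for (j in seq_len(ns)) {
        if (j == i) next
        fj <- fields_by_subject[[j]][[cn]]
        t <- sw_time(fj)
        sel <- t >= centers[[cn]] - window_ms / 2 &
          t <= centers[[cn]] + window_ms / 2
        x <- stats::approx(d$time_ms, d$deriv, xout = t[sel])$y
        pred <- fi$slope * x + fi$intercept
        y <- fj$samples[sel]
        rows[[length(rows) + 1]] <- data.frame(
          condition = cn, fit_subject = i, test_subject = j,
          slope = fi$slope, intercept = fi$intercept,
          r = if (stats::sd(y) > 0 && stats::sd(pred) > 0)
            stats::cor(pred, y) else NA_real_,
          rmse = sqrt(mean((y - pred)^2)))
      }
    }
  }
  folds <- do.call(rbind, rows)
  structure(list(folds = folds, folds_per_condition = ns * (ns - 1)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d folds per condition, %d conditions>\n",
              x$folds_per_condition,
              length(unique(x$folds$condition))))
  cat(sprintf("  median fold r = %.3f, median rmse = %.3g\n",
              stats::median(x$folds$r, na.rm = TRUE),
              stats::median(x$folds$rmse)))
  invisible(x)
}
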
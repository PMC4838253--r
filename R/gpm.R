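#' Lag grid for the coincidence analysis
#'
#' @param lags Strictly increasing vector of positive delays in ms; every lag
#'   must be a multiple of `dt`.
#' @param dt Integration time step in ms (the NAP frame period).
#' @return An object of class `"lag_grid"`.
#' @export
lag_grid <- function(lags, dt) {
  if (dt <= 0) stop("dt must be positive")
  if (any(lags <= 0) || is.unsorted(lags, strictly = TRUE)) {
    stop("lags must be positive and strictly increasing")
  }
  steps <- lags / dt
  if (any(abs(steps - round(steps)) > 1e-6)) {
    stop("lag grid finer than the NAP sampling: lags must be multiples of dt")
  }
  structure(list(lags = lags, dt = dt), class = "lag_grid")
}

#' Default lag grid for a NAP
#'
#' Lags from `lag_min` to `lag_max` at the NAP frame resolution.  The default
#' range 0.125-40 ms covers the 1 ms carrier lag of a 1000 Hz tone as well as
#' sub-envelope lags, while excluding the 50 ms envelope period.
#'
#' @param nap A `"nap"`.
#' @param lag_min,lag_max Lag range in ms.
#' @return A `"lag_grid"`.
#' @export
default_lag_grid <- function(nap, lag_min = 0.125, lag_max = 40) {
  dt <- 1000 / nap$sample_rate_hz
  lag_grid(seq(max(dt, dt * round(lag_min / dt)), lag_max, by = dt), dt)
}

#' Coincidence layer: first stage of the cascade
#'
#' The probability of observing two spikes separated by lag `l`, summed over
#' cochlear channels: `A1(t, l) = sum_k p(t, k) * p(t - l, k)`, with
#' `p(t - l, k)` taken as zero before stimulus onset.
#'
#' @param nap A `"nap"`.
#' @param grid A `"lag_grid"`; defaults to [default_lag_grid()].
#' @return A `"lag_activity"` object of stage 1: list with `stage`, `a`
#'   (time x lag matrix) and `grid`.
#' @export
coincidence <- function(nap, grid = default_lag_grid(nap)) {
  stopifnot(inherits(nap, "nap"), inherits(grid, "lag_grid"))
  p <- nap$p
  n <- nrow(p)
  dt <- 1000 / nap$sample_rate_hz
  if (abs(grid$dt - dt) > 1e-9) {
    stop("lag grid dt must equal the NAP frame period")
  }
  shifts <- round(grid$lags / dt)
  if (max(shifts) >= n) stop("max lag must be shorter than the NAP duration")
  a <- matrix(0, n, length(shifts))
  for (j in seq_along(shifts)) {
    s <- shifts[j]
    a[(s + 1):n, j] <- .rowSums(p[(s + 1):n, , drop = FALSE] *
                                  p[seq_len(n - s), , drop = FALSE],
                                n - s, ncol(p))
  }
  structure(list(stage = 1L, a = a, grid = grid), class = "lag_activity")
}

#' Summary autocorrelation function
#'
#' Exponentially weighted running sum of the coincidence activity over time,
#' `S(t, l) = S(t - dt, l) * exp(-dt/decay) + A1(t, l) * dt`; the final-time
#' lag profile is returned.  This is the static read-out used by classical
#' summary-autocorrelation pitch models.  The default decay of 25 ms spans a
#' good part of a 50 ms modulation cycle, so the summary is meaningful
#' wherever the train ends within its cycle; a few-millisecond decay gives
#' the classical fast running SACF instead.
#'
#' @param a1 A stage-1 `"lag_activity"` from [coincidence()].
#' @param decay_ms Exponential decay time constant in ms.
#' @return List with `sacf` (final lag profile), `grid`, `decay_ms`.
#' @export
sacf <- function(a1, decay_ms = 25) {
  stopifnot(inherits(a1, "lag_activity"), a1$stage == 1L)
  if (decay_ms <= 0) stop("decay_ms must be positive")
  dt <- a1$grid$dt
  w <- exp(-dt / decay_ms)
  prof <- vapply(seq_len(ncol(a1$a)), function(j) {
    s <- stats::filter(a1$a[, j] * dt, w, method = "recursive")
    s[length(s)]
  }, numeric(1))
  list(sacf = as.numeric(prof), grid = a1$grid, decay_ms = decay_ms)
}

#' Effective integration window under top-down gain
#'
#' `E_n = tau_n / (1 + gain)`: with the top-down mechanism inactive
#' (`gain = 0`) the window sits at its nominal time constant; positive gain
#' shrinks it, making the stage track its input faster.
#'
#' @param gain Non-negative top-down gain (`omega_n * lambda_n`).
#' @param tau_n Nominal time constant in ms.
#' @return Effective window in ms, in `(0, tau_n]`.
#' @export
effective_window <- function(gain, tau_n) {
  if (any(gain < 0)) stop("gain must be non-negative")
  if (any(tau_n <= 0)) stop("tau_n must be positive")
  tau_n / (1 + gain)
}

#' Leaky integration stage with a time-varying window
#'
#' Discrete leaky integrator
#' `A_n(t, l) = A_n(t - dt, l) * exp(-dt / E_n(t)) + c_n * A_{n-1}(t, l)`
#' with `A_n(0, l) = 0`.  The decay rate follows the effective window
#' `E_n(t)`, while the drive normalisation `g_n` is a constant fixed by the
#' nominal time constant: it is chosen so that the steady-state response to
#' constant unit input is 1 when the top-down mechanism is inactive
#' (`E_n = tau_n`), giving the drive coefficient
#' `c_n = 1 - exp(-dt / tau_n)`.  This absorbs one factor of `dt` from the
#' raw `dt^2` drive term, so the plateau is invariant under changes of the
#' time step.  With the top-down gain active the plateau becomes
#' approximately `E_n / tau_n < 1`: shrinking the integration window
#' suppresses the stage's output amplitude, which is what couples window
#' adaptation to response magnitude.
#'
#' @param prev A `"lag_activity"` of stage `n - 1`.
#' @param tau_n Nominal time constant in ms: a scalar, or a per-lag vector.
#' @param gain Top-down gain trace: scalar or per-time-step vector (`>= 0`).
#' @param init Initial state `A_n(0, l)`: scalar or per-lag vector.
#' @return A `"lag_activity"` of stage `prev$stage + 1` with an attached
#'   `state`: list with `tau_n`, `e_n` (effective-window trace), `gain` and
#'   `g_n` (the drive normalisation trace implied by the unit-DC convention).
#' @export
integrate_stage <- function(prev, tau_n, gain = 0, init = 0) {
  stopifnot(inherits(prev, "lag_activity"))
  n <- nrow(prev$a)
  l <- ncol(prev$a)
  dt <- prev$grid$dt
  if (length(gain) == 1) gain <- rep(gain, n)
  if (length(gain) != n) stop("gain must be scalar or one value per time step")
  if (any(gain < 0)) stop("gain must be non-negative")
  if (!length(tau_n) %in% c(1L, l)) stop("tau_n must be scalar or per-lag")
  tau_row <- rep_len(tau_n, l)
  a <- matrix(0, n, l)
  e_n <- numeric(n)
  row <- rep_len(init, l)
  drive <- 1 - exp(-dt / tau_row)
  for (t in seq_len(n)) {
    e_row <- tau_row / (1 + gain[t])
    row <- row * exp(-dt / e_row) + drive * prev$a[t, ]
    a[t, ] <- row
    e_n[t] <- e_row[1] # representative trace (shortest-lag window)
  }
  out <- structure(list(stage = prev$stage + 1L, a = a, grid = prev$grid),
                   class = "lag_activity")
  attr(out, "state") <- list(tau_n = tau_n, e_n = e_n, gain = gain,
                             g_n = dt^2 / (tau_row * drive))
  out
}

#' Pick the pitch lag from a lag profile
#'
#' Returns the lag of the highest strictly positive interior local maximum of
#' the profile; ties are broken toward the shortest lag.  The first and last
#' grid bins are excluded: because the underlying activity pattern is a
#' smoothed spike-probability signal, the profile rises toward lag zero as an
#' artifact of within-pulse correlation, and that edge shoulder is not a
#' periodicity peak.  Returns `NA` if no interior peak exists (e.g. silence).
#'
#' @param values Lag profile (one value per grid lag).
#' @param lags Lag vector in ms.
#' @return The peak lag in ms, or `NA_real_`.
#' @export
pick_peak_lag <- function(values, lags) {
  n <- length(values)
  if (n < 3 || all(values <= 0)) return(NA_real_)
  i <- 2:(n - 1)
  is_peak <- values[i] >= values[i - 1] & values[i] >= values[i + 1] &
    (values[i] > values[i - 1] | values[i] > values[i + 1]) & values[i] > 0
  cand <- i[is_peak]
  if (length(cand) == 0) return(NA_real_)
  lags[cand[which.max(values[cand])]]
}

#' Configuration for the hierarchical pitch model
#'
#' @param tau2_min_ms,tau2_max_ms Bounds of the lag-dependent stage-2 time
#'   constant `tau_2(l) = clip(2 l, tau2_min, tau2_max)`.
#' @param tau3_ms Stage-3 time constant in ms (long, `>= 100` ms).
#' @param lag_min_ms,lag_max_ms Lag grid range in ms.
#' @param mismatch_bins Mismatch tolerance of the top-down trigger, in lag
#'   bins.
#' @param stability_ms Stability horizon: a trigger also fires after this long
#'   without any discrepancy.
#' @param gain_max Gain value set on a trigger (windows shrink to
#'   `tau / (1 + gain_max)`).
#' @param relax_ms Relaxation time of the gain back toward zero.
#' @param peak_margin Hysteresis of the controller's committed prediction: a
#'   competing lag peak must exceed the committed peak's activity by this
#'   fraction before the prediction switches.  This keeps near-ties between
#'   subharmonic lag bins (whose activities are equal up to ripple) from
#'   firing spurious mismatches, while genuine collapses of the committed
#'   peak still switch.
#' @param transient_ms Initial span excluded from summary statistics (onset
#'   transient).
#' @param keep_matrices Keep the full time x lag matrices of every stage
#'   (memory heavy).
#' @return A list of class `"gpm_config"`.
#' @export
gpm_config <- function(tau2_min_ms = 2, tau2_max_ms = 100, tau3_ms = 250,
                       lag_min_ms = 0.125, lag_max_ms = 40,
                       mismatch_bins = 1, stability_ms = 250, gain_max = 9,
                       relax_ms = 50, peak_margin = 0.05, transient_ms = 100,
                       keep_matrices = FALSE) {
  structure(as.list(environment()), class = "gpm_config")
}

# a discrepancy requires both predictions defined and separated beyond tol
.lag_jump <- function(a, b, tol) {
  !is.na(a) && !is.na(b) && abs(a - b) > tol
}

# index of the highest strictly positive interior local maximum, or NA
.peak_index <- function(values) {
  n <- length(values)
  if (n < 3 || all(values <= 0)) return(NA_integer_)
  i <- 2:(n - 1)
  is_peak <- values[i] >= values[i - 1] & values[i] >= values[i + 1] &
    (values[i] > values[i - 1] | values[i] > values[i + 1]) & values[i] > 0
  cand <- i[is_peak]
  if (length(cand) == 0) return(NA_integer_)
  cand[which.max(values[cand])]
}

# hysteretic prediction commitment; returns c(new_index, switched)
.commit_peak <- function(cur, row, margin) {
  best <- .peak_index(row)
  if (is.na(best)) return(c(cur, 0))
  if (is.na(cur)) return(c(best, 0))
  if (best != cur && row[best] > row[cur] * (1 + margin)) {
    return(c(best, 1))
  }
  c(cur, 0)
}

# one step of the top-down gain dynamics; returns updated c(gain, timer)
.gain_step <- function(gain, timer, mismatch, dt, config) {
  if (mismatch) {
    c(config$gain_max, 0)
  } else {
    timer <- timer + dt
    if (timer > config$stability_ms) {
      c(config$gain_max, 0)
    } else {
      c(gain * exp(-dt / config$relax_ms), timer)
    }
  }
}

#' Top-down gain trace from a pitch-track history
#'
#' Recomputes the gain `omega_n(t) * lambda_n(t)` that the top-down controller
#' would emit for a given history of lag predictions: the gain jumps to
#' `gain_max` whenever the prediction `L(t)` departs from the expectation
#' `L(t - dt)` by more than the mismatch tolerance, or when no discrepancy has
#' occurred for longer than the stability horizon; otherwise it relaxes
#' exponentially toward zero.  A discrepancy requires both the prediction and
#' the expectation to be defined, so pitch acquisition at stimulus onset does
#' not by itself fire the trigger.
#'
#' @param l3 Lag-prediction history in ms (`NA` where undefined).
#' @param dt Time step in ms.
#' @param config A [gpm_config()].
#' @return Non-negative gain trace, same length as `l3`; causal (the value at
#'   step `t` depends on predictions up to `t - dt`).
#' @export
topdown_controller <- function(l3, dt, config = gpm_config()) {
  n <- length(l3)
  gain <- numeric(n)
  g <- 0
  timer <- 0
  tol <- config$mismatch_bins * dt + 1e-9
  for (t in seq_len(n)) {
    mismatch <- t >= 3 && .lag_jump(l3[t - 1], l3[t - 2], tol)
    st <- .gain_step(g, timer, mismatch, dt, config)
    g <- st[1]
    timer <- st[2]
    gain[t] <- g
  }
  gain
}

#' Run the full adaptive cascade on a NAP
#'
#' Coincidence detection followed by two leaky-integration stages whose
#' effective windows `E_n(t) = tau_n / (1 + gain(t))` are shortened online by
#' the top-down controller.  At every step the lag predictions `L2(t)` and
#' `L3(t)` are read from the stage profiles ([pick_peak_lag()]); a
#' discrepancy between either stage's prediction and its expectation (the
#' prediction one step earlier), or a long stable period, triggers the gain.
#' Because the drive normalisation is fixed by the nominal time constants,
#' shrunken windows also suppress response amplitude, so stimuli whose lag
#' prediction is repeatedly disrupted (the drumming phase of damped cycles)
#' build up less stage-3 activity than stimuli whose strongest drive arrives
#' after a stretch of stable prediction (the rising phase of ramped cycles).
#' The derivative of `A3(t, L3(t))` is the signal later mapped linearly onto
#' evoked-field amplitude.
#'
#' @param nap A `"nap"`.
#' @param config A [gpm_config()].
#' @param adaptive If `FALSE`, the gain is pinned at zero (static windows).
#' @return A list of class `"gpm_fit"` with elements
#'   `track` (class `"pitch_track"`: `time_ms`, `l3`, `pitch`, `expected`,
#'   `salience`, `deriv`), `a1_final`, `a2_final`, `a3_final` (final-time lag
#'   profiles), `gain`, `e2`, `e3` (traces, ms), `grid`, `config`,
#'   `salience_peak`, `salience_peak_ms`, `peak_lag_ms`, and (if
#'   `keep_matrices`) the full `a1`, `a2`, `a3` matrices.
#' @export
run_cascade <- function(nap, config = gpm_config(), adaptive = TRUE) {
  stopifnot(inherits(nap, "nap"), inherits(config, "gpm_config"))
  grid <- default_lag_grid(nap, config$lag_min_ms, config$lag_max_ms)
  a1 <- coincidence(nap, grid)
  dt <- grid$dt
  lags <- grid$lags
  n <- nrow(a1$a)
  l <- length(lags)
  tau2 <- pmin(pmax(2 * lags, config$tau2_min_ms), config$tau2_max_ms)
  tau3 <- config$tau3_ms
  drive2 <- 1 - exp(-dt / tau2)
  drive3 <- 1 - exp(-dt / tau3)

  a2_row <- numeric(l)
  a3_row <- numeric(l)
  l2 <- rep(NA_real_, n)
  l3 <- rep(NA_real_, n)
  sal <- numeric(n)
  gain <- numeric(n)
  e3 <- numeric(n)
  e2_short <- numeric(n)
  g <- 0
  timer <- 0
  tol <- config$mismatch_bins * dt + 1e-9
  keep <- isTRUE(config$keep_matrices)
  if (keep) {
    a2_mat <- matrix(0, n, l)
    a3_mat <- matrix(0, n, l)
  }
  cur2 <- NA_integer_
  cur3 <- NA_integer_
  pending_mismatch <- FALSE

  for (t in seq_len(n)) {
    if (adaptive) {
      st <- .gain_step(g, timer, pending_mismatch, dt, config)
      g <- st[1]
      timer <- st[2]
    }
    gain[t] <- g
    e2_row <- tau2 / (1 + g)
    e3_t <- tau3 / (1 + g)
    a2_row <- a2_row * exp(-dt / e2_row) + drive2 * a1$a[t, ]
    a3_row <- a3_row * exp(-dt / e3_t) + drive3 * a2_row
    if (keep) {
      a2_mat[t, ] <- a2_row
      a3_mat[t, ] <- a3_row
    }
    e2_short[t] <- e2_row[1]
    e3[t] <- e3_t
    # committed (hysteretic) predictions drive the mismatch monitor
    c2 <- .commit_peak(cur2, a2_row, config$peak_margin)
    c3 <- .commit_peak(cur3, a3_row, config$peak_margin)
    jump2 <- c2[2] == 1 &&
      .lag_jump(lags[c2[1]], lags[cur2], tol)
    jump3 <- c3[2] == 1 &&
      .lag_jump(lags[c3[1]], lags[cur3], tol)
    pending_mismatch <- jump2 || jump3
    cur2 <- c2[1]
    cur3 <- c3[1]
    l2[t] <- if (is.na(cur2)) NA_real_ else lags[cur2]
    pk <- pick_peak_lag(a3_row, lags)
    l3[t] <- pk
    sal[t] <- if (is.na(pk)) 0 else a3_row[which(lags == pk)]
  }

  time_ms <- (seq_len(n) - 1) * dt
  deriv <- c(0, diff(sal)) / dt
  track <- structure(list(time_ms = time_ms, l3 = l3, l2 = l2,
                          pitch = 1 / l3,
                          expected = 1 / c(NA_real_, l3[-n]),
                          salience = sal, deriv = deriv, dt = dt),
                     class = "pitch_track")
  post <- time_ms >= config$transient_ms
  sal_post <- sal[post]
  pk_t <- which.max(sal_post)
  out <- list(track = track,
              a1_final = a1$a[n, ], a2_final = a2_row, a3_final = a3_row,
              gain = gain, e2 = e2_short, e3 = e3,
              grid = grid, config = config, adaptive = adaptive,
              salience_peak = max(sal_post),
              salience_peak_ms = time_ms[post][pk_t],
              peak_lag_ms = pick_peak_lag(a3_row, lags))
  if (keep) {
    out$a1 <- a1$a
    out$a2 <- a2_mat
    out$a3 <- a3_mat
  }
  structure(out, class = "gpm_fit")
}

#' Static-window control model
#'
#' The same cascade with the top-down gain pinned at zero, so that
#' `E_n(t) = tau_n` throughout: an autocorrelation-style model with fixed
#' integration windows.
#'
#' @inheritParams run_cascade
#' @return A `"gpm_fit"`, as [run_cascade()].
#' @export
static_window_control <- function(nap, config = gpm_config()) {
  run_cascade(nap, config, adaptive = FALSE)
}

#' @export
print.gpm_fit <- function(x, ...) {
  cat(sprintf("<gpm_fit: %s windows, peak lag %.3g ms, salience peak %.4g>\n",
              if (x$adaptive) "adaptive" else "static",
              x$peak_lag_ms, x$salience_peak))
  invisible(x)
}

#' Linear prediction of evoked-field amplitude from the model derivative
#'
#' Applies a fitted linear map to the derivative of `A3(t, L3(t))` over a
#' requested time window.
#'
#' @param track A `"pitch_track"` from [run_cascade()].
#' @param slope,intercept Linear-map coefficients.
#' @param window_ms Length-2 numeric, time window in ms (default: whole
#'   track).
#' @return List with `time_ms` and `predicted`.
#' @export
n100m_predictor <- function(track, slope = 1, intercept = 0,
                            window_ms = NULL) {
  stopifnot(inherits(track, "pitch_track"))
  if (is.null(window_ms)) window_ms <- range(track$time_ms)
  if (window_ms[1] < min(track$time_ms) - 1e-9 ||
      window_ms[2] > max(track$time_ms) + 1e-9) {
    stop("window outside the track")
  }
  sel <- track$time_ms >= window_ms[1] & track$time_ms <= window_ms[2]
  list(time_ms = track$time_ms[sel],
       predicted = slope * track$deriv[sel] + intercept)
}
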
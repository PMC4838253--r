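test_that("lag grids validate spacing against the NAP resolution", {
  expect_error(lag_grid(c(0.1, 0.2), dt = 0.125), "multiples")
  expect_error(lag_grid(c(0.25, 0.125), dt = 0.125), "increasing")
  expect_error(lag_grid(c(0.125, 0.25), dt = 0), "positive")
  g <- lag_grid(seq(0.125, 40, 0.125), 0.125)
  expect_length(g$lags, 320)
})

test_that("coincidence matches the brute-force double loop to machine precision", {
  set.seed(7)
  p <- matrix(runif(200 * 5), 200, 5)
  nap <- nap_from_matrix(p, fs = 8000)
  grid <- lag_grid(seq(0.125, 5, 0.125), 0.125)
  a1 <- coincidence(nap, grid)
  brute <- matrix(0, 200, length(grid$lags))
  for (t in 1:200) {
    for (j in seq_along(grid$lags)) {
      s <- round(grid$lags[j] / 0.125)
      if (t - s >= 1) {
        acc <- 0
        for (k in 1:5) acc <- acc + p[t, k] * p[t - s, k]
        brute[t, j] <- acc
      }
    }
  }
  expect_equal(a1$a, brute, tolerance = 1e-14)
})

test_that("coincidence closed forms: silence and constant patterns", {
  z <- coincidence(nap_from_matrix(matrix(0, 100, 4)), lag_grid(c(0.125, 1), 0.125))
  expect_true(all(z$a == 0))
  cst <- coincidence(nap_from_matrix(matrix(0.3, 100, 4)),
                     lag_grid(seq(0.125, 2, 0.125), 0.125))
  late <- cst$a[(round(2 / 0.125) + 1):100, ]
  expect_equal(unique(as.numeric(late)), 4 * 0.3^2, tolerance = 1e-12)
})

test_that("coincidence rejects lags beyond the NAP or finer than its sampling", {
  nap <- nap_from_matrix(matrix(1, 50, 2))
  expect_error(coincidence(nap, lag_grid(c(0.125, 10), 0.125)), "duration")
  expect_error(coincidence(nap, lag_grid(0.0625, 0.0625)), "frame period")
})

test_that("SACF of zero input is zero and constant input hits its plateau", {
  z <- sacf(make_stage1(matrix(0, 50, 3)))
  expect_true(all(z$sacf == 0))
  a1 <- make_stage1(matrix(2, 4000, 3))
  s <- sacf(a1, decay_ms = 2.5)
  w <- exp(-0.125 / 2.5)
  plateau <- 2 * 0.125 / (1 - w)
  expect_equal(s$sacf, rep(plateau, 3), tolerance = 1e-6)
  expect_error(sacf(a1, decay_ms = 0), "positive")
})

test_that("SACF of the carrier stimuli peaks at the 1 ms carrier lag", {
  for (ty in c("ramped", "damped")) {
    a1 <- coincidence(small_nap(ty, 4))
    s <- sacf(a1)
    expect_equal(pick_peak_lag(s$sacf, s$grid$lags), 1)
  }
})

test_that("effective window shrinks as tau/(1+gain)", {
  expect_equal(effective_window(0, 100), 100)
  expect_equal(effective_window(1, 100), 50)
  expect_equal(effective_window(3, 100), 25)
  expect_error(effective_window(-1, 100), "non-negative")
  expect_error(effective_window(1, 0), "positive")
})

test_that("integrator decays freely as exp(-t/E) with zero drive", {
  n <- 400
  prev <- make_stage1(matrix(0, n, 2))
  out <- integrate_stage(prev, tau_n = 10, gain = 0, init = 5)
  t_ms <- (1:n) * 0.125
  expect_equal(out$a[, 1], 5 * exp(-t_ms / 10), tolerance = 1e-10)
})

test_that("integrator reaches the algebraic fixed point under constant drive", {
  dt <- 0.125
  n <- 6000
  drive_val <- 3
  prev <- make_stage1(matrix(drive_val, n, 2), dt)
  for (gain in c(0, 3)) {
    out <- integrate_stage(prev, tau_n = 20, gain = gain)
    e <- 20 / (1 + gain)
    fixed <- drive_val * (1 - exp(-dt / 20)) / (1 - exp(-dt / e))
    expect_equal(out$a[n, 1], fixed, tolerance = 1e-6)
    if (gain == 0) expect_equal(fixed, drive_val, tolerance = 1e-12)
    st <- attr(out, "state")
    expect_true(all(st$e_n <= 20 + 1e-12 & st$e_n > 0))
  }
})

test_that("the plateau is invariant under halving the time step", {
  run_dt <- function(dt, gain) {
    n <- round(800 / dt)
    prev <- make_stage1(matrix(1, n, 1), dt)
    integrate_stage(prev, tau_n = 20, gain = gain)$a[n, 1]
  }
  expect_equal(run_dt(0.125, 0), run_dt(0.0625, 0), tolerance = 1e-9)
  expect_equal(run_dt(0.125, 3), run_dt(0.0625, 3), tolerance = 0.01)
})

test_that("pitch read-out finds the highest interior peak, shortest on ties", {
  lags <- seq(0.125, 5, 0.125)
  v <- rep(0.1, length(lags))
  v[8] <- 1
  v[16] <- 1 # equal peak at a longer lag
  expect_equal(pick_peak_lag(v, lags), 1)
  v[16] <- 2
  expect_equal(pick_peak_lag(v, lags), 2)
  # monotone shoulder toward short lags is not a peak
  v2 <- rev(seq_along(lags)) / length(lags)
  expect_true(is.na(pick_peak_lag(v2, lags)))
  expect_true(is.na(pick_peak_lag(rep(0, length(lags)), lags)))
})

test_that("controller gain stays at zero for a short stable track and jumps on a step", {
  cfg <- gpm_config()
  stable <- rep(1, 800) # 100 ms at 0.125 ms: below the stability horizon
  g <- topdown_controller(stable, 0.125, cfg)
  expect_true(all(g == 0))
  stepped <- c(rep(1, 400), rep(2, 400))
  g2 <- topdown_controller(stepped, 0.125, cfg)
  expect_equal(max(g2), cfg$gain_max)
  i_jump <- which(g2 == cfg$gain_max)[1]
  expect_equal(i_jump, 402) # causal: reacts one step after the change
  expect_true(all(diff(g2[(i_jump + 1):800]) <= 0))
  expect_true(all(g2 >= 0))
})

test_that("a long stable period also fires the trigger (stability horizon)", {
  cfg <- gpm_config(stability_ms = 30)
  g <- topdown_controller(rep(1, 800), 0.125, cfg)
  expect_equal(max(g), cfg$gain_max)
  expect_gt(sum(g == cfg$gain_max), 1) # refires periodically
})

test_that("silence yields a silent cascade", {
  nap <- nap_from_matrix(matrix(0, 600, 4))
  fit <- run_cascade(nap, gpm_config(lag_max_ms = 10, transient_ms = 10))
  expect_true(all(fit$a3_final == 0))
  expect_equal(fit$salience_peak, 0)
  expect_true(all(is.na(fit$track$l3)))
})

test_that("adaptive and static cascades agree when the controller never triggers", {
  # constant NAP: lag profiles are monotone, no interior peak ever forms,
  # so no discrepancy can fire and the windows stay at tau
  nap <- nap_from_matrix(matrix(0.2, 800, 3))
  cfg <- gpm_config(lag_max_ms = 10, transient_ms = 10)
  ad <- run_cascade(nap, cfg)
  st <- static_window_control(nap, cfg)
  expect_equal(ad$a3_final, st$a3_final, tolerance = 1e-12)
  expect_true(all(ad$gain == 0))
  expect_equal(ad$e3, rep(cfg$tau3_ms, 800))
})

test_that("effective windows never exceed their nominal time constants", {
  fit <- condition_pipeline("damped", 4)$adaptive
  cfg <- fit$config
  expect_true(all(fit$e3 > 0 & fit$e3 <= cfg$tau3_ms + 1e-12))
  expect_true(all(fit$e2 > 0 & fit$e2 <= cfg$tau2_min_ms + 1e-12))
  tau2 <- pmin(pmax(2 * fit$grid$lags, cfg$tau2_min_ms), cfg$tau2_max_ms)
  expect_true(all(tau2 >= 2 & tau2 <= 100))
})

test_that("the cascade matches composed integrate_stage calls in static mode", {
  set.seed(11)
  p <- matrix(runif(300 * 3), 300, 3)
  nap <- nap_from_matrix(p)
  cfg <- gpm_config(lag_max_ms = 5, transient_ms = 5)
  fit <- static_window_control(nap, cfg)
  a1 <- coincidence(nap, default_lag_grid(nap, cfg$lag_min_ms, cfg$lag_max_ms))
  tau2 <- pmin(pmax(2 * a1$grid$lags, cfg$tau2_min_ms), cfg$tau2_max_ms)
  a2 <- integrate_stage(a1, tau2)
  a3 <- integrate_stage(a2, cfg$tau3_ms)
  expect_equal(fit$a3_final, a3$a[300, ], tolerance = 1e-12)
})

test_that("the linear evoked-field predictor is affine in the derivative", {
  fit <- run_cascade(nap_from_matrix(matrix(0.2, 400, 2)),
                     gpm_config(lag_max_ms = 5, transient_ms = 5))
  pred <- n100m_predictor(fit$track, slope = 1, intercept = 0)
  expect_equal(pred$predicted, fit$track$deriv)
  pred2 <- n100m_predictor(fit$track, slope = 0, intercept = 4,
                           window_ms = c(10, 20))
  expect_true(all(pred2$predicted == 4))
  expect_error(n100m_predictor(fit$track, window_ms = c(10, 1e5)), "window")
})
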
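flat_epoch <- function(fill = 0) {
  source_waveform(rep(fill, 1900), 1000, -500)
}

gauss_epoch <- function(depth = -30, latency = 100, sigma = 15, noise = 0,
                        drift = 0, offset = 0, sf = 0) {
  t <- seq(-500, 1399)
  x <- depth * exp(-(t - latency)^2 / (2 * sigma^2)) +
    sf * (t > 300 & t < 1050) + offset + drift * (t + 500) / 1000
  if (noise > 0) x <- x + rnorm(length(t), 0, noise)
  source_waveform(x, 1000, -500)
}

test_that("preprocessing leaves a clean epoch unchanged and removes offsets", {
  w <- gauss_epoch()
  expect_equal(preprocess_epoch(w)$samples, w$samples, tolerance = 1e-6)
  wo <- gauss_epoch(offset = 12.5)
  expect_equal(preprocess_epoch(wo)$samples, gauss_epoch()$samples,
               tolerance = 1e-6)
})

test_that("injected linear drift is removed almost completely", {
  slope <- 7
  wd <- gauss_epoch(drift = slope)
  cln <- preprocess_epoch(wd)
  t <- sw_time(cln)
  tail <- t >= 1300
  resid <- stats::lm(cln$samples[tail] ~ t[tail])$coefficients[2] * 1000
  expect_lt(abs(resid) / slope, 0.05)
  expect_equal(cln$samples, gauss_epoch()$samples, tolerance = 1e-6)
})

test_that("the N100m measurement recovers an injected deflection exactly", {
  m <- measure_n100m(preprocess_epoch(gauss_epoch(-30, 100)))
  expect_equal(m$amplitude, -30, tolerance = 1e-6)
  expect_equal(m$latency_ms, 100)
  expect_false(m$flagged)
  expect_equal(m$magnitude, 30, tolerance = 1e-6)
})

test_that("flat epochs are flagged and equal minima resolve to the earliest", {
  m <- measure_n100m(flat_epoch())
  expect_equal(m$amplitude, 0)
  expect_true(m$flagged)
  t <- seq(-500, 1399)
  x <- numeric(length(t))
  x[t == 80] <- -5
  x[t == 120] <- -5
  m2 <- measure_n100m(source_waveform(x, 1000, -500))
  expect_equal(m2$latency_ms, 80)
})

test_that("sustained-field depth is the mean over the inclusive window", {
  w <- flat_epoch()
  w$samples[sw_time(w) >= 800 & sw_time(w) <= 1000] <- -20
  sf <- measure_sf(w)
  expect_equal(sf$depth, -20)
  expect_equal(sf$n, 201)
  expect_equal(measure_sf(flat_epoch())$depth, 0)
})

test_that("pooled samples have 31 and 201 points per subject at 1 kHz", {
  waves <- list(gauss_epoch(-30), gauss_epoch(-25))
  expect_length(pooled_sample(waves[1], "n100m"), 31)
  expect_length(pooled_sample(waves[1], "sf"), 201)
  expect_length(pooled_sample(waves, "n100m"), 62)
  expect_length(pooled_sample(waves, "sf"), 402)
  bad <- waves
  bad[[2]]$sample_rate_hz <- 500
  expect_error(pooled_sample(bad, "n100m"), "sampling rates")
})

test_that("rank-sum comparison behaves across null and separated samples", {
  x <- rnorm(100)
  expect_gt(compare_conditions(x, x)$p, 0.99)
  set.seed(31)
  a <- rnorm(100)
  b <- rnorm(100) + 5
  expect_lt(compare_conditions(a, b)$p, 0.001)
  # rank statistic invariant under monotone transforms
  expect_equal(compare_conditions(exp(a), exp(b))$statistic,
               compare_conditions(a, b)$statistic)
  expect_error(compare_conditions(numeric(0), a), "empty")
})

test_that("Pearson correlation returns exact r for exact linear relations", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  expect_equal(correlate(x, -x)$r, -1)
  expect_error(correlate(x, rep(1, 10)), "zero-variance")
  expect_error(correlate(1:3, 1:4), "equal length")
})

test_that("the linear map recovers exact and noisy injected coefficients", {
  t_model <- seq(0, 400, by = 0.5)
  deriv <- sin(t_model / 20) * exp(-t_model / 150)
  t_field <- seq(-500, 1399)
  dint <- approx(t_model, deriv, xout = t_field, rule = 2)$y
  field <- source_waveform(3 * dint - 7, 1000, -500)
  fit <- fit_linear_map(t_model, deriv, field, center_ms = 100)
  expect_equal(fit$slope, 3, tolerance = 1e-6)
  expect_equal(fit$intercept, -7, tolerance = 1e-6)
  expect_equal(fit$rmse, 0, tolerance = 1e-6)
  set.seed(8)
  noisy <- field
  amp <- sd(field$samples)
  noisy$samples <- field$samples + rnorm(1900, 0, 0.1 * amp)
  fitn <- fit_linear_map(t_model, deriv, noisy, center_ms = 100)
  expect_lt(abs(fitn$slope - 3) / 3, 0.15)
  expect_lt(abs(fitn$intercept + 7) / 7, 0.15)
  const <- source_waveform(rep(1, 1900), 1000, -500)
  expect_error(fit_linear_map(t_model, rep(1, length(t_model)), const,
                              center_ms = 100), "rank-deficient")
})

test_that("cross-validation produces N(N-1) folds and degenerate cases behave", {
  t_model <- seq(0, 400, by = 0.5)
  deriv <- -exp(-(t_model - 100)^2 / 450)
  derivs <- list(cond_a = list(time_ms = t_model, deriv = deriv))
  mk <- function(mult) {
    w <- gauss_epoch(-30 * mult, 100)
    list(cond_a = w)
  }
  two <- list(mk(1), mk(1.3))
  cv <- cross_validate(two, derivs)
  expect_equal(cv$folds_per_condition, 2)
  expect_equal(nrow(cv$folds), 2)
  identical3 <- list(mk(1), mk(1), mk(1))
  cv3 <- cross_validate(identical3, derivs)
  self_rmse <- fit_linear_map(t_model, deriv, identical3[[1]]$cond_a,
                              center_ms = 100)$rmse
  expect_equal(cv3$folds$rmse, rep(self_rmse, 6), tolerance = 1e-8)
  expect_error(cross_validate(two[1], derivs), "at least 2")
})
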
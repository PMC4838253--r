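test_that("damped envelope has peak 1/T and halves every half-life", {
  expect_equal(envelope(0, 4, "damped"), 0.25)
  expect_equal(envelope(4, 4, "damped") / envelope(0, 4, "damped"), 0.5)
  expect_equal(envelope(8, 4, "damped") / envelope(0, 4, "damped"), 0.25)
  expect_true(all(envelope(seq(0, 49.9, 0.1), 0.5, "ramped") > 0))
})

test_that("envelope rejects out-of-cycle times and bad half-lives", {
  expect_error(envelope(50, 4, "damped"), "cycle")
  expect_error(envelope(-1, 4, "damped"), "cycle")
  expect_error(envelope(10, 0, "damped"), "positive")
  expect_error(envelope(10, -2, "ramped"), "positive")
})

test_that("a 20-cycle 50 ms train lasts exactly one second", {
  w <- synthesize_train(stimulus_spec(1000, 4, "ramped"))
  expect_length(w$samples, 48000)
  expect_equal(length(w$samples) / w$sample_rate_hz, 1)
})

test_that("cycle boundaries sit on upward-going carrier zero crossings", {
  for (ty in c("ramped", "damped")) {
    w <- synthesize_train(stimulus_spec(1000, 4, ty))
    i <- 2400 * (1:19) + 1 # sample index of t = k * 50 ms
    expect_true(all(abs(w$samples[i]) < 1e-12))
    expect_true(all(w$samples[i + 1] > w$samples[i]))
  }
})

test_that("sampled damped envelope is the elementwise reverse of the ramped one", {
  fs <- 48000
  u <- ((0:2399) + 0.5) * 1000 / fs
  for (hl in c(0.5, 4, 32)) {
    ed <- envelope(u, hl, "damped")
    er <- envelope(u, hl, "ramped")
    expect_equal(rev(er), ed, tolerance = 1e-12)
  }
})

test_that("phase alignment is rejected for non-integer carrier periods per cycle", {
  expect_error(stimulus_spec(carrier_hz = 1010), "integer")
  expect_silent(stimulus_spec(carrier_hz = 1020))
})

test_that("ramped and damped partners share the long-term magnitude spectrum", {
  for (hl in c(0.5, 4, 32)) {
    sr <- Mod(stats::fft(synthesize_condition("ramped", hl)$samples))
    sd <- Mod(stats::fft(synthesize_condition("damped", hl)$samples))
    expect_lt(sqrt(sum((sr - sd)^2) / sum(sd^2)), 0.05)
  }
})

test_that("level normalization scales with the square root of the half-life", {
  w <- waveform(rep(1, 100), 48000)
  a16 <- normalize_level(w, 16, level_ref = 2)$samples[1]
  a4 <- normalize_level(w, 4, level_ref = 2)$samples[1]
  expect_equal(a16 / a4, 2)
  z <- normalize_level(waveform(rep(0, 100), 48000), 4, level_ref = 1)
  expect_true(all(z$samples == 0))
  expect_error(normalize_level(w, -1, level_ref = 1), "positive")
})

test_that("normalized stimuli have equal RMS within ten percent", {
  conds <- stimulus_conditions()
  rms <- vapply(seq_len(nrow(conds)), function(i) {
    w <- synthesize_condition(conds$envelope_type[i], conds$half_life_ms[i])
    sqrt(mean(w$samples^2))
  }, numeric(1))
  expect_lt(max(rms) / min(rms), 1.1)
})

test_that("envelope periodicity matches the cycle and carrier the carrier", {
  w <- synthesize_condition("damped", 4, n_cycles = 4)
  s <- Mod(stats::fft(abs(w$samples)))
  freqs <- (seq_along(s) - 1) * 48000 / length(s)
  half <- freqs > 1 & freqs < 24000
  # rectified signal: strongest line at the 20 Hz envelope rate region or
  # harmonics; check 20 Hz line well above neighbouring non-harmonic bins
  i20 <- which.min(abs(freqs - 20))
  i13 <- which.min(abs(freqs - 13))
  expect_gt(s[i20], 10 * s[i13])
  sc <- Mod(stats::fft(w$samples))
  expect_equal(freqs[half][which.max(sc[half])], 1000, tolerance = 0.01)
})

test_that("asymmetry index is the normalized ramped-damped contrast", {
  expect_equal(asymmetry_index(3, 3), 0)
  expect_equal(asymmetry_index(5, 0), 1)
  expect_equal(asymmetry_index(3, 1), 0.5)
  expect_error(asymmetry_index(0, 0), "undefined")
})

test_that("asymmetry index is antisymmetric and bounded", {
  set.seed(42)
  for (k in 1:50) {
    x <- runif(2, 0, 10)
    if (sum(x) == 0) next
    ai <- asymmetry_index(x[1], x[2])
    expect_equal(ai, -asymmetry_index(x[2], x[1]))
    expect_true(ai >= -1 && ai <= 1)
  }
})

test_that("wav files round-trip through the header we write", {
  w <- synthesize_condition("damped", 4, n_cycles = 1)
  path <- tempfile(fileext = ".wav")
  write_wav(w, path)
  con <- file(path, "rb")
  on.exit(close(con))
  expect_identical(readChar(con, 4), "RIFF")
  invisible(readBin(con, integer(), 1, size = 4))
  expect_identical(readChar(con, 8), "WAVEfmt ")
  invisible(readBin(con, integer(), 1, size = 4)) # fmt chunk size
  invisible(readBin(con, integer(), 2, size = 2)) # PCM, mono
  expect_identical(readBin(con, integer(), 1, size = 4), 48000L)
  expect_identical(file.size(path), 44 + 2 * length(w$samples))
})
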
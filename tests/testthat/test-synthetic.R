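test_that("the default ground truth is valid, deterministic and 4 ms-peaked", {
  gt <- default_ground_truth()
  expect_s3_class(gt, "ground_truth")
  expect_identical(gt, default_ground_truth())
  expect_equal(gt$n_subjects, 27)
  expect_length(gt$btl_strengths, 10)
  expect_equal(sum(gt$btl_strengths), 1)
  # asymmetry of the hemisphere-averaged amplitude surface peaks at 4 ms
  m_avg <- apply(gt$m0, c(1, 2), mean)
  ai <- asymmetry_index(m_avg["ramped", ], m_avg["damped", ])
  expect_equal(gt$half_lives_ms[which.max(ai)], 4)
  ai_s <- salience_ai(gt$btl_strengths)
  expect_equal(ai_s$half_life_ms[which.max(ai_s$ai)], 4)
})

test_that("ground-truth invariants are enforced", {
  gt <- default_ground_truth()
  bad <- gt
  bad$m0["ramped", "16", "left"] <- 1 # breaks monotonicity
  expect_error(validate_ground_truth(bad), "non-decreasing")
  bad2 <- gt
  bad2$m0["damped", "32", "left"] <- 35 # still monotone, but > ramped's 34
  expect_error(validate_ground_truth(bad2), "ramped")
  bad3 <- gt
  bad3$m0["ramped", "1", "right"] <- bad3$m0["ramped", "1", "right"] + 2
  expect_error(validate_ground_truth(bad3), "4 ms")
  bad4 <- gt
  bad4$btl_strengths[1] <- -0.1
  expect_error(validate_ground_truth(bad4), "positive")
})

test_that("waveform generation is reproducible and seed-sensitive", {
  gt <- default_ground_truth()
  gt$n_subjects <- 2
  a <- synth_subject_waveforms(gt, seed = 7)
  b <- synth_subject_waveforms(gt, seed = 7)
  expect_identical(a, b)
  c <- synth_subject_waveforms(gt, seed = 8)
  expect_false(identical(a$waveforms[[1]]$samples, c$waveforms[[1]]$samples))
  expect_equal(length(a$waveforms), 2 * 2 * 10)
  expect_equal(nrow(a$index), 40)
  t <- sw_time(a$waveforms[[1]])
  expect_equal(range(t), c(-500, 1399))
})

test_that("noise-free generation lets the N100m measurement recover the surface exactly", {
  gt <- default_ground_truth()
  gt$n_subjects <- 2
  gt$noise_sd <- 0
  gt$drift_range <- 0
  gt$subject_jitter_sd <- 0
  gt$latency_jitter_sd_ms <- 0
  set <- synth_subject_waveforms(gt, seed = 1)
  for (i in c(1, 8, 25)) {
    row <- set$index[i, ]
    m <- measure_n100m(preprocess_epoch(set$waveforms[[row$i]]))
    truth <- gt$m0[row$envelope_type, as.character(row$half_life_ms),
                   row$hemisphere]
    expect_equal(m$magnitude, truth, tolerance = 1e-3)
    expect_equal(m$latency_ms, unname(gt$latency_ms[[row$envelope_type]]))
  }
})

test_that("sustained-field depth is recovered within two standard errors", {
  gt <- default_ground_truth()
  set <- synth_subject_waveforms(gt, seed = 3)
  cond <- "ramped_16"
  waves <- subject_waveforms_avg(set, cond)
  depths <- vapply(waves, function(w) measure_sf(w)$depth, numeric(1))
  jitter_mean <- exp(gt$subject_jitter_sd^2 / 2) # lognormal subject factor
  truth <- -gt$sf_frac * mean(gt$m0["ramped", "16", ]) * jitter_mean
  se <- stats::sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - truth), 2 * se + 0.05 * abs(truth))
})

test_that("synthetic win tables have the right shape and fair-coin limit", {
  gt <- default_ground_truth()
  tab <- synth_paired_comparisons(gt, seed = 11)
  expect_equal(dim(tab$wins), c(10, 10))
  expect_true(all(diag(tab$wins) == 0))
  expect_true(all(tab$wins + t(tab$wins) - diag(diag(tab$wins)) >= 0))
  off <- tab$wins + t(tab$wins)
  expect_true(all(off[upper.tri(off)] == 2 * gt$trials_per_pair))
  eq <- gt
  eq$btl_strengths[] <- 1 / 10
  tab_eq <- synth_paired_comparisons(eq, seed = 4, trials_per_pair = 500)
  rates <- tab_eq$wins / (tab_eq$wins + t(tab_eq$wins))
  expect_lt(max(abs(rates[upper.tri(rates)] - 0.5)), 0.06)
})

test_that("BTL fitting recovers the ground-truth strength ordering", {
  gt <- default_ground_truth()
  tab <- synth_paired_comparisons(gt, seed = 21, trials_per_pair = 40)
  fit <- btl_fit(tab)
  # rank agreement: adjacent near-ties may swap, the ordering must not scramble
  expect_gte(cor(rank(fit$strengths), rank(gt$btl_strengths),
                 method = "spearman"), 0.9)
})

test_that("end-to-end strength recovery stays within 20 percent over seeds", {
  gt <- default_ground_truth()
  rel_err <- vapply(1:10, function(s) {
    tab <- synth_paired_comparisons(gt, seed = 100 + s, trials_per_pair = 40)
    fit <- btl_fit(tab)
    max(abs(fit$strengths - gt$btl_strengths) / gt$btl_strengths)
  }, numeric(1))
  expect_lt(mean(rel_err), 0.2)
})
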
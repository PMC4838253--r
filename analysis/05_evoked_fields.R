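#!/usr/bin/env Rscript
# Evoked-field quantification on the synthetic cohort: 27 subjects, two
# hemispheres, ten conditions.  Epochs are baseline- and drift-corrected,
# the N100m transient (minimum in 50-200 ms) and the sustained field
# (mean over 800-1000 ms) are measured, and rank-sum statistics are pooled
# over the peak neighbourhood (31 samples/subject -> n = 837) or the
# sustained window (201 samples/subject -> n = 5427).

library(tempasym)
dir.create("results", showWarnings = FALSE)
seed <- 42

gt <- default_ground_truth()
set <- synth_subject_waveforms(gt, seed = seed)
meas <- measure_all(set)
write.table(meas, "results/n100m_measurements.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# hemisphere-averaged grand means and asymmetry indices
gm <- aggregate(cbind(magnitude, sf_depth, latency_ms) ~
                  envelope_type + half_life_ms, meas, mean)
write.table(gm, "results/n100m_grand_means.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
hls <- sort(unique(gm$half_life_ms))
ai_m <- vapply(hls, function(hl) {
  asymmetry_index(gm$magnitude[gm$envelope_type == "ramped" &
                                 gm$half_life_ms == hl],
                  gm$magnitude[gm$envelope_type == "damped" &
                                 gm$half_life_ms == hl])
}, numeric(1))

# pooled ramped-vs-damped rank-sum per half-life (hemisphere-averaged)
p_rd <- vapply(hls, function(hl) {
  wr <- subject_waveforms_avg(set, condition_id("ramped", hl))
  wd <- subject_waveforms_avg(set, condition_id("damped", hl))
  compare_conditions(pooled_sample(wr, "n100m"),
                     pooled_sample(wd, "n100m"))$p
}, numeric(1))
ai_tab <- data.frame(half_life_ms = hls, ai_m = ai_m,
                     p_ramped_vs_damped = p_rd, n_pooled = 27 * 31)
write.table(ai_tab, "results/n100m_asymmetry.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# per-hemisphere contrasts
hc <- hemisphere_contrast(set)
write.table(hc$ai, "results/hemisphere_asymmetry.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(hc$lr, "results/hemisphere_leftright.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

message(sprintf("N100m magnitude grows with half-life; AI_M maximal at %g ms (AI = %.2f, p = %.2g, n = %d)",
                hls[which.max(ai_m)], max(ai_m),
                p_rd[which.max(ai_m)], 27 * 31))
r4 <- hc$ai[hc$ai$half_life_ms == 4, ]
message(sprintf("4 ms ramped-vs-damped contrast: right p = %.2g, left p = %.2g (right-lateralized)",
                r4$p_ramped_vs_damped[r4$hemisphere == "right"],
                r4$p_ramped_vs_damped[r4$hemisphere == "left"]))
message("wrote results/n100m_*.tsv, results/hemisphere_*.tsv")
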
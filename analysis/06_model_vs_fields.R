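#!/usr/bin/env Rscript
# Links the three measurement domains:
#  - Pearson correlation between the fitted salience scale and the grand-mean
#    N100m magnitudes,
#  - correlation between the two models' salience predictions and both,
#  - cross-validated linear mapping from the derivative of the cascade's
#    top-stage activity onto the evoked transient (fit on one subject, test
#    on the remaining 26: 702 folds per condition).
# Requires the tables written by 03, 04 and 05.

library(tempasym)
dir.create("results", showWarnings = FALSE)
seed <- 42

model <- read.delim("results/model_salience.tsv")
btl <- read.delim("results/btl_scale.tsv")
btl10 <- read.delim("results/btl_scale_replicates.tsv")
gm <- read.delim("results/n100m_grand_means.tsv")

key <- condition_id(gm$envelope_type, gm$half_life_ms)
m_mag <- gm$magnitude
s_btl <- btl$strength[match(key, btl$condition)]
s_btl10 <- btl10$strength[match(key, btl10$condition)]
s_gpm <- model$gpm_salience[match(key, model$condition)]
s_sai <- model$sai_salience[match(key, model$condition)]

row_cor <- function(name, x, y) {
  ct <- correlate(x, y)
  data.frame(pair = name, r = ct$r, p = ct$p)
}
cors <- rbind(
  row_cor("salience_vs_n100m", s_btl, m_mag),
  row_cor("salience_replicates_vs_n100m", s_btl10, m_mag),
  row_cor("sai_vs_salience_replicates", s_sai, s_btl10),
  row_cor("gpm_vs_n100m", s_gpm, m_mag))
write.table(cors, "results/cross_domain_correlations.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("salience scale vs N100m magnitude: r = %.3f (one experiment), r = %.3f (ten replicates)",
                cors$r[1], cors$r[2]))

# cross-validated linear map from model derivative to evoked transient
gt <- default_ground_truth()
set <- synth_subject_waveforms(gt, seed = seed)
conds <- stimulus_conditions()
derivs <- lapply(seq_len(nrow(conds)), function(i) {
  d <- read.delim(sprintf("results/deriv/%s.tsv", conds$condition[i]))
  list(time_ms = d$time_ms, deriv = d$deriv)
})
names(derivs) <- conds$condition
# per-condition hemisphere-averaged preprocessed waveforms, regrouped by subject
fields <- local({
  per_cond <- lapply(conds$condition, function(cn) subject_waveforms_avg(set, cn))
  names(per_cond) <- conds$condition
  lapply(seq_len(gt$n_subjects), function(s) {
    lapply(per_cond, function(ws) ws[[s]])
  })
})

cv <- cross_validate(fields, derivs)
write.table(cv$folds, "results/crossval_folds.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("cross-validation: %d folds per condition; median |r| = %.2f, median RMSE = %.3g",
                cv$folds_per_condition, median(abs(cv$folds$r), na.rm = TRUE),
                median(cv$folds$rmse)))
message("wrote results/cross_domain_correlations.tsv, results/crossval_folds.tsv")
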
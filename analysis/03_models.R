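#!/usr/bin/env Rscript
# Pitch-model simulations for all ten conditions:
#  - the hierarchical cascade with adaptive (top-down modulated) integration
#    windows, plus the static-window autocorrelation control,
#  - the strobed-integration auditory image.
# Writes per-condition salience measures, asymmetry indices per half-life,
# and the derivative of the top-stage activity at the predicted pitch
# (used later to predict evoked-field morphology).

library(tempasym)
dir.create("results", showWarnings = FALSE)
dir.create("results/deriv", showWarnings = FALSE)

conds <- stimulus_conditions()
rows <- list()
for (i in seq_len(nrow(conds))) {
  ty <- conds$envelope_type[i]
  hl <- conds$half_life_ms[i]
  message("running models for ", conds$condition[i], " ...")
  w <- synthesize_condition(ty, hl)
  nap <- auditory_periphery(w)
  ad <- run_cascade(nap)
  st <- static_window_control(nap)
  strobes <- detect_strobes(nap)
  sai <- build_sai(nap, strobes)
  ch <- which.min(abs(nap$cfs - 1000))
  rows[[i]] <- data.frame(
    condition = conds$condition[i],
    envelope_type = ty, half_life_ms = hl,
    gpm_peak_lag_ms = ad$peak_lag_ms,
    gpm_salience = ad$salience_peak,
    gpm_static_salience = st$salience_peak,
    mean_gain = mean(ad$gain),
    sai_peak_interval_ms = sai_peak_interval(sai),
    sai_salience = carrier_salience(sai, 1000),
    strobes_mid_channel = length(strobes$times_ms[[ch]]),
    nap_energy = nap_energy(nap))
  write.table(
    data.frame(time_ms = ad$track$time_ms, deriv = ad$track$deriv,
               salience = ad$track$salience),
    sprintf("results/deriv/%s.tsv", conds$condition[i]),
    sep = "\t", row.names = FALSE, quote = FALSE)
}
tab <- do.call(rbind, rows)
write.table(tab, "results/model_salience.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

ai <- do.call(rbind, lapply(c(0.5, 1, 4, 16, 32), function(hl) {
  r <- tab[tab$envelope_type == "ramped" & tab$half_life_ms == hl, ]
  d <- tab[tab$envelope_type == "damped" & tab$half_life_ms == hl, ]
  data.frame(half_life_ms = hl,
             ai_gpm = asymmetry_index(r$gpm_salience, d$gpm_salience),
             ai_gpm_static = asymmetry_index(r$gpm_static_salience,
                                             d$gpm_static_salience),
             ai_sai = asymmetry_index(r$sai_salience, d$sai_salience),
             ai_nap = asymmetry_index(r$nap_energy, d$nap_energy))
}))
write.table(ai, "results/model_asymmetry.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

message("all conditions peak at the carrier lag: ",
        all(tab$gpm_peak_lag_ms == 1),
        " (cascade), image peak at -1 ms: ",
        all(tab$sai_peak_interval_ms == -1))
i4 <- ai$half_life_ms == 4
message(sprintf(
  "4 ms asymmetry: adaptive cascade %.2f vs static control %.2f; image %.2f vs nerve %.2f",
  ai$ai_gpm[i4], ai$ai_gpm_static[i4], ai$ai_sai[i4], ai$ai_nap[i4]))
message("wrote results/model_salience.tsv, results/model_asymmetry.tsv, results/deriv/")
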
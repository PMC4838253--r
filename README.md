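# tempasym

Tools for studying how the auditory system tells a sound from its time
reverse.  Ramped and damped sinusoids — a 1 kHz carrier multiplied by a
periodically rising or decaying exponential envelope — have identical
long-term spectra yet sound very different: ramped trains are heard as a
continuous tone, damped trains as drumming with weaker tonal (pitch)
salience.  The package implements, as tested R code, the full analysis
chain that links this temporal asymmetry to perception and to the N100m
deflection of auditory evoked fields:

* **Stimulus synthesis.** Trains of 20 cycles of 50 ms (total 1 s) with
  envelope half-lives T½ ∈ {0.5, 1, 4, 16, 32} ms, each cycle starting at
  an upward-going zero crossing of the carrier, levels normalized ∝ √T½.
  The damped envelope is E(t) = (1/T½)·exp(−t·ln2/T½); the ramped envelope
  is its within-cycle time reverse.
* **Auditory periphery.** Gammatone filterbank (100 ERB-spaced channels,
  100–10000 Hz) and a functional hair-cell model (rectification, 0.6
  power-law compression, 1.2 kHz low-pass, divisive adaptation) yielding a
  neural activity pattern p(t, k) at 8 kHz.
* **Hierarchical pitch model with adaptive integration windows.** A
  coincidence layer A₁(t, l) = Σₖ p(t,k)·p(t−l,k) followed by two leaky
  integrators with effective windows Eₙ(t) = τₙ/(1 + ωₙ(t)λₙ(t)); a
  top-down controller shrinks the windows (and thereby suppresses
  amplitude) whenever the lag prediction disagrees with its expectation.
  A static-window variant serves as the autocorrelation control.
* **Auditory image model.** Adaptive-threshold strobe detection and
  strobed temporal integration into a stabilised auditory image with 30 ms
  buffer decay; pitch salience is the height of the summary-image ridge at
  the carrier period.
* **Psychophysics.** Paired-comparison schedules (45 pairs in both orders)
  and maximum-likelihood Bradley–Terry–Luce scaling,
  P(i beats j) = Sᵢ/(Sᵢ+Sⱼ).
* **Evoked-field analysis.** Baseline/drift correction, N100m peak and
  sustained-field measurement, pooled Wilcoxon rank-sum statistics,
  hemispheric contrasts, and a cross-validated linear map from the model's
  top-stage derivative to evoked amplitude (N(N−1) = 702 folds for 27
  subjects).
* **Synthetic cohort.** A seeded generator producing source waveforms and
  choice data with the qualitative structure of the modelled experiment,
  so the whole chain runs and is tested without human recordings.

The asymmetry index used throughout is AIₓ = (x_r − x_d)/(x_r + x_d).

## Worked example

```r
library(tempasym)

## a 4 ms ramped/damped pair through the periphery and both models
run <- function(type) {
  nap <- auditory_periphery(synthesize_condition(type, 4))
  list(gpm = run_cascade(nap),
       sai = build_sai(nap, detect_strobes(nap)))
}
r <- run("ramped"); d <- run("damped")

r$gpm
#> <gpm_fit: adaptive windows, peak lag 1 ms, salience peak 0.003107>
d$gpm
#> <gpm_fit: adaptive windows, peak lag 1 ms, salience peak 0.00152>

sai_peak_interval(r$sai)
#> [1] -1
asymmetry_index(carrier_salience(r$sai), carrier_salience(d$sai))
#> [1] 0.7162117
```

Both models place their activity maximum at the 1 ms lag — the carrier
period, i.e. both "hear" the 1 kHz pitch — while the ramped member yields
the larger salience: the cascade's 4 ms asymmetry index is 0.34 under
adaptive windows versus 0.05 for the static-window control, and the
strobed image amplifies the nerve-level asymmetry (0.05) to 0.72.

The numbered scripts under `analysis/` run the complete study on the
synthetic cohort and write tab-separated tables under `results/`:

```sh
Rscript analysis/01_stimuli.R          # stimulus checks (RMS spread 6.5%)
Rscript analysis/02_periphery.R        # NAP summaries per condition
Rscript analysis/03_models.R           # both pitch models, all 10 conditions
Rscript analysis/04_psychophysics.R    # BTL scale and salience asymmetry
Rscript analysis/05_evoked_fields.R    # N100m / sustained-field statistics
Rscript analysis/06_model_vs_fields.R  # cross-domain correlations, 702-fold CV
```

On the default synthetic cohort (27 subjects, seed 42) these print, among
other things: N100m magnitude growing with half-life and AI maximal at
4 ms (pooled ramped-vs-damped p = 7.8e−28, n = 837); a ramped/damped
contrast at 4 ms present in the right hemisphere (p = 7.6e−85) but not the
left (p = 0.18); and a Pearson correlation of r = 0.97 between the
replicate-averaged salience scale and the N100m magnitudes.

## Layout

```
R/                  package code (stimuli, periphery, gpm, aim,
                    psychophysics, aef, synthetic generator)
analysis/           numbered narrative drivers over the package
scripts/            acceptance script
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (model equations, parameter choices,
                    numerical conventions, limitations)
```
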
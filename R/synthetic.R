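#' Default ground truth for the synthetic experiment
#'
#' Encodes the qualitative pattern the analysis chain is built to detect:
#' N100m magnitude grows with envelope half-life for both envelope types,
#' ramped responses are at least as large as damped ones everywhere, the
#' ramped/damped difference peaks at the 4 ms half-life, and the extra
#' right-hemisphere ramped/damped contrast exists only at 4 ms.  Ramped
#' N100m latencies are delayed relative to damped ones, the sustained field
#' is a fixed fraction of the N100m surface, and the paired-comparison
#' strengths follow the same ordering as the evoked amplitudes so that
#' salience and field magnitude are co-monotone by construction.
#'
#' Magnitudes are in the nAm-like units of the source waveforms.  Defaults:
#' 27 subjects, 10 conditions, 13 listeners contributing one judgement per
#' ordered pair.
#'
#' @return An object of class `"ground_truth"`; see the field list in the
#'   source for the exact defaults.
#' @export
default_ground_truth <- function() {
  hl <- c(0.5, 1, 4, 16, 32)
  m0 <- array(0, c(2, 5, 2),
              dimnames = list(type = c("ramped", "damped"),
                              half_life = as.character(hl),
                              hemisphere = c("left", "right")))
  m0["damped", , "left"] <- c(10, 14, 20, 28, 32)
  m0["ramped", , "left"] <- c(11, 16, 20, 31, 34) # no left contrast at 4 ms
  m0[, , "right"] <- m0[, , "left"] + 2
  m0["ramped", "4", "right"] <- m0["ramped", "4", "right"] + 10
  s <- c(0.05, 0.08, 0.14, 0.15, 0.16, 0.04, 0.06, 0.08, 0.13, 0.15)
  names(s) <- condition_id(rep(c("ramped", "damped"), each = 5), rep(hl, 2))
  gt <- structure(list(
    half_lives_ms = hl,
    m0 = m0,
    latency_ms = c(ramped = 115, damped = 100),
    latency_jitter_sd_ms = 3,
    n100m_sigma_ms = 15,
    sf_frac = 0.6,
    sf_rise = c(center_ms = 330, sd_ms = 40),
    sf_fall = c(center_ms = 1080, sd_ms = 30),
    noise_sd = 3,
    drift_range = 10,          # units per second, uniform in +/- range
    subject_jitter_sd = 0.2,   # sd of log multiplicative subject factor
    btl_strengths = s / sum(s),
    n_subjects = 27,
    trials_per_pair = 13,      # judgements per ordered pair
    epoch_ms = c(-500, 1399),
    sample_rate_hz = 1000
  ), class = "ground_truth")
  validate_ground_truth(gt)
  gt
}

#' Validate a ground-truth object
#'
#' Checks the structural invariants: magnitudes non-decreasing in half-life
#' within each type and hemisphere, ramped >= damped everywhere, the
#' right-minus-left ramped/damped contrast nonzero only at the 4 ms
#' half-life, and positive choice strengths.
#'
#' @param gt A `"ground_truth"`.
#' @return `gt`, invisibly; errors if an invariant fails.
#' @export
validate_ground_truth <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  for (ty in c("ramped", "damped")) {
    for (h in c("left", "right")) {
      if (is.unsorted(gt$m0[ty, , h])) {
        stop("m0 must be non-decreasing in half-life (", ty, ", ", h, ")")
      }
    }
  }
  if (any(gt$m0["ramped", , ] < gt$m0["damped", , ])) {
    stop("m0(ramped) must be >= m0(damped)")
  }
  contrast <- (gt$m0["ramped", , "right"] - gt$m0["damped", , "right"]) -
    (gt$m0["ramped", , "left"] - gt$m0["damped", , "left"])
  nz <- which(contrast != 0)
  if (!identical(as.character(gt$half_lives_ms[nz]), "4")) {
    stop("hemispheric contrast must be nonzero only at the 4 ms half-life")
  }
  if (any(gt$btl_strengths <= 0)) stop("BTL strengths must be positive")
  invisible(gt)
}

#' Generate synthetic per-subject source waveforms
#'
#' For every subject, hemisphere and condition the epoch is assembled as
#' baseline zero, a negative Gaussian N100m deflection (depth taken from the
#' ground-truth surface with a subject-level multiplicative factor, latency
#' from the per-type latency plus jitter), a smoothed-rectangle sustained
#' plateau spanning roughly 300-1050 ms, a linear drift with a random slope,
#' and additive white Gaussian noise.  All randomness flows from `seed`, so
#' repeated calls are identical.
#'
#' @param gt A `"ground_truth"`.
#' @param seed Integer seed.
#' @return An `"aef_set"`: list with `waveforms` (list of
#'   [source_waveform()]s), `index` (data frame with subject, hemisphere,
#'   condition, envelope_type, half_life_ms) and `ground_truth`.
#' @export
synth_subject_waveforms <- function(gt, seed = 1) {
  validate_ground_truth(gt)
  set.seed(seed)
  fs <- gt$sample_rate_hz
  t <- seq(gt$epoch_ms[1], gt$epoch_ms[2], by = 1000 / fs)
  n <- length(t)
  plateau <- stats::pnorm(t, gt$sf_rise["center_ms"], gt$sf_rise["sd_ms"]) *
    (1 - stats::pnorm(t, gt$sf_fall["center_ms"], gt$sf_fall["sd_ms"]))
  jit <- exp(stats::rnorm(gt$n_subjects, 0, gt$subject_jitter_sd))
  waveforms <- list()
  idx <- list()
  for (s in seq_len(gt$n_subjects)) {
    for (h in c("left", "right")) {
      for (ty in c("ramped", "damped")) {
        for (hi in seq_along(gt$half_lives_ms)) {
          hlab <- as.character(gt$half_lives_ms[hi])
          m <- gt$m0[ty, hlab, h] * jit[s]
          lat <- gt$latency_ms[[ty]] +
            stats::rnorm(1, 0, gt$latency_jitter_sd_ms)
          slope <- stats::runif(1, -gt$drift_range, gt$drift_range)
          noise <- stats::rnorm(n, 0, gt$noise_sd)
          x <- -m * exp(-(t - lat)^2 / (2 * gt$n100m_sigma_ms^2)) -
            gt$sf_frac * m * plateau +
            slope * (t - gt$epoch_ms[1]) / 1000 + noise
          cid <- condition_id(ty, gt$half_lives_ms[hi])
          waveforms[[length(waveforms) + 1]] <-
            source_waveform(x, fs, gt$epoch_ms[1], subject = s,
                            hemisphere = h, condition = cid)
          idx[[length(idx) + 1]] <- data.frame(
            i = length(waveforms), subject = s, hemisphere = h,
            condition = cid, envelope_type = ty,
            half_life_ms = gt$half_lives_ms[hi])
        }
      }
    }
  }
  structure(list(waveforms = waveforms, index = do.call(rbind, idx),
                 ground_truth = gt),
            class = "aef_set")
}

#' @export
print.aef_set <- function(x, ...) {
  cat(sprintf("<aef_set: %d waveforms (%d subjects x %d hemispheres x %d conditions)>\n",
              length(x$waveforms), length(unique(x$index$subject)),
              length(unique(x$index$hemisphere)),
              length(unique(x$index$condition))))
  invisible(x)
}

#' Select waveforms from an aef_set
#'
#' @param set An `"aef_set"`.
#' @param subject,hemisphere,condition Optional filters.
#' @return List of `"source_waveform"`s.
#' @export
sw_select <- function(set, subject = NULL, hemisphere = NULL,
                      condition = NULL) {
  sel <- rep(TRUE, nrow(set$index))
  if (!is.null(subject)) sel <- sel & set$index$subject %in% subject
  if (!is.null(hemisphere)) sel <- sel & set$index$hemisphere %in% hemisphere
  if (!is.null(condition)) sel <- sel & set$index$condition %in% condition
  set$waveforms[set$index$i[sel]]
}

#' Generate a synthetic paired-comparison win table
#'
#' Every unordered pair of the 10 conditions is presented
#' `2 * trials_per_pair` times (both orders of the 45 pairs); each
#' presentation is a Bernoulli draw with `P(i beats j) = S_i / (S_i + S_j)`
#' from the ground-truth strengths.
#'
#' @param gt A `"ground_truth"`.
#' @param seed Integer seed.
#' @param trials_per_pair Judgements per ordered pair; default from `gt`.
#' @return A `"paired_comparisons"` win table.
#' @export
synth_paired_comparisons <- function(gt, seed = 1,
                                     trials_per_pair = gt$trials_per_pair) {
  validate_ground_truth(gt)
  set.seed(seed)
  s <- gt$btl_strengths
  n <- length(s)
  wins <- matrix(0L, n, n, dimnames = list(names(s), names(s)))
  sched <- pair_schedule(n)
  unordered <- unique(t(apply(as.matrix(sched), 1, sort)))
  for (r in seq_len(nrow(unordered))) {
    i <- unordered[r, 1]
    j <- unordered[r, 2]
    total <- 2L * as.integer(trials_per_pair)
    w <- stats::rbinom(1, total, s[i] / (s[i] + s[j]))
    wins[i, j] <- w
    wins[j, i] <- total - w
  }
  paired_comparisons(wins)
}
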
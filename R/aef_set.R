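#' Measure N100m and sustained field across a waveform set
#'
#' Preprocesses every epoch ([preprocess_epoch()]) and measures the N100m
#' and the sustained field, returning one row per waveform.
#'
#' @param set An `"aef_set"`.
#' @return Data frame: subject, hemisphere, condition, envelope_type,
#'   half_life_ms, amplitude, magnitude, latency_ms, flagged, sf_depth.
#' @export
measure_all <- function(set) {
  stopifnot(inherits(set, "aef_set"))
  rows <- lapply(seq_along(set$waveforms), function(i) {
    w <- preprocess_epoch(set$waveforms[[i]])
    m <- measure_n100m(w)
    sf <- measure_sf(w)
    cbind(set$index[i, c("subject", "hemisphere", "condition",
                         "envelope_type", "half_life_ms")],
          data.frame(amplitude = m$amplitude, magnitude = m$magnitude,
                     latency_ms = m$latency_ms, flagged = m$flagged,
                     sf_depth = sf$depth))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-subject hemisphere-averaged preprocessed waveforms
#'
#' @param set An `"aef_set"`.
#' @param condition Condition id.
#' @return List over subjects of `"source_waveform"`s (`hemisphere = "avg"`).
#' @export
subject_waveforms_avg <- function(set, condition) {
  subjects <- sort(unique(set$index$subject))
  lapply(subjects, function(s) {
    wl <- sw_select(set, subject = s, hemisphere = "left",
                    condition = condition)[[1]]
    wr <- sw_select(set, subject = s, hemisphere = "right",
                    condition = condition)[[1]]
    preprocess_epoch(average_hemispheres(wl, wr))
  })
}

#' Grand-mean source waveform over subjects
#'
#' @param set An `"aef_set"`.
#' @param condition Condition id.
#' @param hemisphere `"left"`, `"right"` or `"avg"`.
#' @return A `"source_waveform"` (preprocessed average).
#' @export
grand_mean_waveform <- function(set, condition, hemisphere = "avg") {
  subjects <- sort(unique(set$index$subject))
  waves <- lapply(subjects, function(s) {
    if (hemisphere == "avg") {
      wl <- sw_select(set, s, "left", condition)[[1]]
      wr <- sw_select(set, s, "right", condition)[[1]]
      preprocess_epoch(average_hemispheres(wl, wr))
    } else {
      preprocess_epoch(sw_select(set, s, hemisphere, condition)[[1]])
    }
  })
  out <- waves[[1]]
  out$samples <- rowMeans(vapply(waves, function(w) w$samples,
                                 numeric(length(out$samples))))
  out$subject <- NA
  out
}

#' Hemispheric contrast analysis
#'
#' For each hemisphere and half-life: the asymmetry index of the grand-mean
#' N100m magnitudes, the ramped-vs-damped rank-sum test on the pooled
#' per-subject peak-window samples, and the left-vs-right rank-sum test per
#' condition.
#'
#' @param set An `"aef_set"`.
#' @return List with `ai` (data frame: hemisphere, half_life_ms, m_ramped,
#'   m_damped, ai, p_ramped_vs_damped) and `lr` (data frame: condition,
#'   p_left_vs_right).
#' @export
hemisphere_contrast <- function(set) {
  stopifnot(inherits(set, "aef_set"))
  hls <- sort(unique(set$index$half_life_ms))
  subjects <- sort(unique(set$index$subject))
  pre <- function(h, cond) {
    lapply(subjects, function(s) {
      preprocess_epoch(sw_select(set, s, h, cond)[[1]])
    })
  }
  ai_rows <- list()
  for (h in c("left", "right")) {
    for (hl in hls) {
      wr <- pre(h, condition_id("ramped", hl))
      wd <- pre(h, condition_id("damped", hl))
      mr <- mean(vapply(wr, function(w) measure_n100m(w)$magnitude, 1))
      md <- mean(vapply(wd, function(w) measure_n100m(w)$magnitude, 1))
      pv <- compare_conditions(pooled_sample(wr, "n100m"),
                               pooled_sample(wd, "n100m"))$p
      ai_rows[[length(ai_rows) + 1]] <- data.frame(
        hemisphere = h, half_life_ms = hl, m_ramped = mr, m_damped = md,
        ai = asymmetry_index(mr, md), p_ramped_vs_damped = pv)
    }
  }
  conds <- unique(set$index$condition)
  lr_rows <- lapply(conds, function(cond) {
    wl <- pre("left", cond)
    wr <- pre("right", cond)
    data.frame(condition = cond,
               p_left_vs_right = compare_conditions(
                 pooled_sample(wl, "n100m"), pooled_sample(wr, "n100m"))$p)
  })
  list(ai = do.call(rbind, ai_rows), lr = do.call(rbind, lr_rows))
}
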
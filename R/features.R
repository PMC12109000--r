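#' Canonical feature column order of the model input
#'
#' The fixed ordering of the model-input slots: the 22 canonical
#' time-series features of the PPG, PPG mean and SD, pulse arrival time and
#' heart rate, four PPG morphology features, age and sex (32 slots), plus the
#' calibration-segment ABP mean and SD in personalized mode (34 slots). The
#' order is stored with every trained estimator and enforced at prediction.
#'
#' @param mode `"calibration_free"` (32 columns) or `"personalized"` (34).
#' @return Character vector of column names.
#' @export
feature_column_order <- function(mode = c("calibration_free",
                                          "personalized")) {
  mode <- match.arg(mode)
  base <- c(
    catch22_feature_names(),
    "ppg_mean", "ppg_sd", "pat", "heart_rate",
    "t_valley_to_peak", "t_peak_to_next_valley",
    "ppg_peak_amplitude", "ppg_upslope", "age", "sex"
  )
  if (mode == "personalized") {
    base <- c(base, "cal_abp_mean", "cal_abp_sd")
  }
  base
}

#' Pulse arrival time and heart rate of a segment
#'
#' PAT is the mean of the first three R-peak-to-following-PPG-valley (pulse
#' foot) intervals; heart rate is 60 divided by the mean of the same three
#' consecutive R-R intervals.
#'
#' @param segment A [waveform_segment()].
#' @param ann [annotate_segment()] output with >= 4 R peaks and >= 3
#'   following PPG valleys.
#' @return `list(pat, heart_rate)` in seconds and beats/min.
#' @export
temporal_features <- function(segment, ann) {
  r <- ann$r_peaks
  v <- ann$ppg_valleys
  if (length(r) < 4) {
    stop("need >= 4 R peaks for temporal features (segment should have ",
         "failed QC)")
  }
  fs <- segment$fs
  # pair each R peak with its ensuing pulse foot; a foot more than 0.5 s
  # later belongs to a subsequent beat (the foot of the very first beat is
  # undetectable under the min-between-peaks convention), so such R peaks
  # are skipped
  pat_all <- vapply(seq_along(r), function(i) {
    nxt <- v[v > r[i]]
    if (!length(nxt)) {
      return(NA_real_)
    }
    (nxt[1] - r[i]) / fs
  }, numeric(1))
  valid <- which(!is.na(pat_all) & pat_all <= 0.5)
  if (length(valid) < 3 || valid[3] + 1 > length(r)) {
    stop("fewer than 3 usable R-peak/PPG-valley pairs")
  }
  use <- valid[1:3]
  rr <- (r[use + 1] - r[use]) / fs
  list(pat = mean(pat_all[use]), heart_rate = 60 / mean(rr))
}

# pair each valley-to-next-valley interval with the systolic peak inside it
complete_ppg_beats <- function(ann) {
  v <- ann$ppg_valleys
  p <- ann$ppg_peaks
  if (length(v) < 2) {
    return(NULL)
  }
  beats <- lapply(seq_len(length(v) - 1), function(j) {
    inside <- p[p > v[j] & p < v[j + 1]]
    if (!length(inside)) {
      return(NULL)
    }
    c(valley = v[j], peak = inside[1], next_valley = v[j + 1])
  })
  beats <- do.call(rbind, beats[!vapply(beats, is.null, logical(1))])
  beats
}

#' PPG pulse morphology features
#'
#' Averages, over three randomly chosen successive complete beats, the
#' valley-to-peak time, the peak-to-next-valley time, the pulse amplitude
#' (peak minus valley value), and the upslope (amplitude over valley-to-peak
#' time). The starting beat of the triple is drawn uniformly under `seed`,
#' so the choice is reproducible.
#'
#' @param segment A [waveform_segment()].
#' @param ann [annotate_segment()] output with >= 4 complete PPG beats.
#' @param seed Selection seed.
#' @return `list(t_valley_to_peak, t_peak_to_next_valley,
#'   ppg_peak_amplitude, ppg_upslope)`.
#' @export
morphology_features <- function(segment, ann, seed = 1L) {
  beats <- complete_ppg_beats(ann)
  if (is.null(beats) || nrow(beats) < 4) {
    stop("need >= 4 complete PPG beats for morphology features")
  }
  start <- with_seed(seed, sample(nrow(beats) - 2, 1))
  b <- beats[start:(start + 2), , drop = FALSE]
  fs <- segment$fs
  ppg <- segment$ppg
  t_up <- (b[, "peak"] - b[, "valley"]) / fs
  t_down <- (b[, "next_valley"] - b[, "peak"]) / fs
  amp <- ppg[b[, "peak"]] - ppg[b[, "valley"]]
  list(
    t_valley_to_peak = mean(t_up),
    t_peak_to_next_valley = mean(t_down),
    ppg_peak_amplitude = mean(amp),
    ppg_upslope = mean(amp / t_up)
  )
}

#' Build one labeled model-input example from a segment
#'
#' Assembles the full feature vector of a segment (22 canonical time-series
#' features of the PPG, PPG mean/SD, PAT, heart rate, four morphology
#' features, age, sex; plus the calibration-segment ABP mean/SD in
#' personalized mode) together with the segment's reference SBP/DBP targets.
#'
#' In personalized mode the calibration values must come from a different,
#' earlier segment of the same subject: passing calibration data whose `t0`
#' is not strictly earlier than the segment's raises a protocol-violation
#' error.
#'
#' @param segment A [waveform_segment()].
#' @param ann Matching [annotate_segment()] output.
#' @param demographics `list(age, sex)`; defaults to the segment's metadata.
#' @param mode `"calibration_free"` or `"personalized"`.
#' @param cal_abp For personalized mode: `list(mean, sd, t0)` with the ABP
#'   waveform mean and SD of the calibration segment and that segment's t0.
#' @param seed Seed for the morphology beat-triple selection.
#' @return An object of class `labeled_example`: `list(features (named),
#'   target_sbp, target_dbp, subject_id, t0)`.
#' @export
build_example <- function(segment, ann, demographics = NULL,
                          mode = c("calibration_free", "personalized"),
                          cal_abp = NULL, seed = 1L) {
  mode <- match.arg(mode)
  demographics <- demographics %||% list(age = segment$age,
                                         sex = segment$sex)
  if (mode == "personalized") {
    if (is.null(cal_abp)) {
      stop("personalized mode requires cal_abp from an earlier segment")
    }
    if (!is.null(cal_abp$t0) && cal_abp$t0 >= segment$t0) {
      stop(
        "protocol violation: calibration ABP must come from a strictly ",
        "earlier segment (cal t0=", cal_abp$t0, ", segment t0=",
        segment$t0, ")"
      )
    }
  }
  c22 <- catch22_features(segment$ppg)
  tf <- temporal_features(segment, ann)
  mf <- morphology_features(segment, ann, seed = seed)
  feats <- c(
    c22,
    ppg_mean = mean(segment$ppg), ppg_sd = sd(segment$ppg),
    pat = tf$pat, heart_rate = tf$heart_rate,
    t_valley_to_peak = mf$t_valley_to_peak,
    t_peak_to_next_valley = mf$t_peak_to_next_valley,
    ppg_peak_amplitude = mf$ppg_peak_amplitude,
    ppg_upslope = mf$ppg_upslope,
    age = as.numeric(demographics$age), sex = as.numeric(demographics$sex)
  )
  if (mode == "personalized") {
    feats <- c(feats, cal_abp_mean = cal_abp$mean, cal_abp_sd = cal_abp$sd)
  }
  feats <- feats[feature_column_order(mode)]
  ref <- reference_bp(segment$abp, ann)
  structure(
    list(
      features = feats, target_sbp = ref$sbp, target_dbp = ref$dbp,
      subject_id = segment$subject_id, t0 = segment$t0, mode = mode
    ),
    class = "labeled_example"
  )
}

# ABP-waveform calibration summary of a segment
cal_summary <- function(segment) {
  list(mean = mean(segment$abp), sd = sd(segment$abp), t0 = segment$t0)
}

# stack labeled examples into a modelling data.frame
examples_to_frame <- function(examples) {
  feats <- do.call(rbind, lapply(examples, `[[`, "features"))
  df <- as.data.frame(feats)
  df$target_sbp <- vapply(examples, `[[`, numeric(1), "target_sbp")
  df$target_dbp <- vapply(examples, `[[`, numeric(1), "target_dbp")
  df$subject_id <- vapply(examples, `[[`, character(1), "subject_id")
  df$t0 <- vapply(examples, `[[`, numeric(1), "t0")
  df
}
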
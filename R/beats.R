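moving_average <- function(x, w) {
  y <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  y[is.na(y)] <- mean(x)
  y
}

bandpass <- function(x, fs, low, high, order = 2) {
  ny <- fs / 2
  bf <- signal::butter(order, c(low / ny, high / ny), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Detect ECG R peaks (Pan-Tompkins)
#'
#' QRS detection following the Pan-Tompkins scheme: 5-15 Hz band-pass
#' (zero-phase Butterworth), differentiation, squaring, 150 ms
#' moving-window integration, and adaptive peak/noise thresholding with a
#' 200 ms refractory period. Detections are refined to the local maximum of
#' the raw ECG within +/-100 ms of each integrated-signal peak.
#'
#' @param ecg Numeric ECG series (>= 2 s of samples).
#' @param fs Sampling rate, Hz.
#' @return Integer vector of 1-based R-peak sample indices (possibly empty).
#' @export
detect_r_peaks <- function(ecg, fs) {
  if (length(ecg) < 2 * fs) {
    warning("ECG series shorter than 2 s; no peaks detected")
    return(integer(0))
  }
  if (stats::sd(ecg) == 0) {
    return(integer(0))
  }
  bp <- bandpass(ecg, fs, 5, 15)
  der <- c(0, diff(bp))
  sq <- der^2
  mwi <- moving_average(sq, max(3L, round(0.150 * fs)))

  refr <- round(0.200 * fs)
  n <- length(mwi)
  # candidate local maxima of the integrated signal
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (!length(cand)) {
    return(integer(0))
  }
  # adaptive signal/noise levels (initialized from the first 2 s)
  spki <- max(mwi[seq_len(2 * fs)]) * 0.5
  npki <- mean(mwi[seq_len(2 * fs)]) * 0.5
  peaks <- integer(0)
  mwi_floor <- 0.05 * max(mwi)
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[i] > thr && mwi[i] > mwi_floor) {
      if (length(peaks) && (i - peaks[length(peaks)]) < refr) {
        # within refractory period: keep the larger of the two
        if (mwi[i] > mwi[peaks[length(peaks)]]) {
          peaks[length(peaks)] <- i
        }
        next
      }
      peaks <- c(peaks, i)
      spki <- 0.125 * mwi[i] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
  }
  if (!length(peaks)) {
    return(integer(0))
  }
  # refine to the raw-ECG maximum near each integrated peak
  half <- round(0.100 * fs)
  refined <- vapply(peaks, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    as.integer(lo + which.max(ecg[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # collapse refinements that landed within one refractory period,
  # keeping the largest R wave of each cluster
  keep <- integer(0)
  for (i in refined) {
    if (length(keep) && (i - keep[length(keep)]) < refr) {
      if (ecg[i] > ecg[keep[length(keep)]]) keep[length(keep)] <- i
    } else {
      keep <- c(keep, i)
    }
  }
  keep
}

#' Detect PPG systolic peaks and diastolic valleys (Elgendi)
#'
#' Systolic peaks are located with the two-moving-average event-detection
#' scheme: band-pass 0.5-8 Hz, clip negative values, square, and compare a
#' W1 = 111 ms peak moving average against a W2 = 667 ms beat moving average
#' offset by beta = 0.02 times the mean squared signal; blocks wider than W1
#' yield one peak each. Diastolic valleys are the minima between consecutive
#' systolic peaks, per the upstream convention.
#'
#' @param ppg Numeric PPG series (>= 2 s of samples).
#' @param fs Sampling rate, Hz.
#' @return `list(peaks, valleys)` of 1-based sample indices; `valleys` is
#'   empty when fewer than two peaks are found.
#' @export
detect_ppg_landmarks <- function(ppg, fs) {
  if (length(ppg) < 2 * fs) {
    warning("PPG series shorter than 2 s; no landmarks detected")
    return(list(peaks = integer(0), valleys = integer(0)))
  }
  if (stats::sd(ppg) == 0) {
    return(list(peaks = integer(0), valleys = integer(0)))
  }
  filt <- bandpass(ppg, fs, 0.5, 8)
  clipped <- pmax(filt, 0)
  sq <- clipped^2
  w1 <- max(3L, round(0.111 * fs))
  w2 <- max(w1 + 2L, round(0.667 * fs))
  ma_peak <- moving_average(sq, w1)
  ma_beat <- moving_average(sq, w2)
  thr1 <- ma_beat + 0.02 * mean(sq)
  block <- ma_peak > thr1
  edges <- diff(c(FALSE, block, FALSE))
  starts <- which(edges == 1)
  ends <- which(edges == -1) - 1L
  keep <- (ends - starts + 1L) >= w1
  starts <- starts[keep]
  ends <- ends[keep]
  if (!length(starts)) {
    return(list(peaks = integer(0), valleys = integer(0)))
  }
  peaks <- mapply(function(s, e) s + which.max(ppg[s:e]) - 1L, starts, ends)
  peaks <- sort(unique(as.integer(peaks)))
  # guard against zero-phase filter warm-up transients at the segment start
  peaks <- peaks[peaks > round(0.4 * fs)]
  # a genuine systolic peak is a local maximum of the raw signal; block
  # maxima that sit on a block edge (monotone stretches, end transients)
  # are discarded
  n_ppg <- length(ppg)
  peaks <- peaks[peaks > 1 & peaks < n_ppg]
  peaks <- peaks[ppg[peaks] >= ppg[peaks - 1] & ppg[peaks] >= ppg[peaks + 1]]
  if (length(peaks) < 2) {
    return(list(peaks = peaks, valleys = integer(0)))
  }
  valleys <- vapply(seq_len(length(peaks) - 1), function(j) {
    lo <- peaks[j]
    hi <- peaks[j + 1]
    lo + which.min(ppg[lo:hi]) - 1L
  }, integer(1))
  list(peaks = peaks, valleys = as.integer(valleys))
}

#' Detect all beat landmarks of a segment
#'
#' Runs R-peak detection on the ECG, landmark detection on the PPG, and
#' pulse landmark detection on the ABP channel; per-beat systolic and
#' diastolic pressures are the extremes of the ABP between consecutive pulse
#' onsets (valleys).
#'
#' @param segment A [waveform_segment()].
#' @return An object of class `beat_annotations` with elements `r_peaks`,
#'   `ppg_peaks`, `ppg_valleys`, `abp_peaks`, `abp_valleys`,
#'   `abp_systolic`, `abp_diastolic`.
#' @export
annotate_segment <- function(segment) {
  stopifnot(inherits(segment, "waveform_segment"))
  r <- detect_r_peaks(segment$ecg, segment$fs)
  pl <- detect_ppg_landmarks(segment$ppg, segment$fs)
  al <- detect_ppg_landmarks(segment$abp, segment$fs)
  sys <- dia <- numeric(0)
  if (length(al$valleys) >= 2) {
    nv <- length(al$valleys)
    sys <- vapply(seq_len(nv - 1), function(j) {
      max(segment$abp[al$valleys[j]:al$valleys[j + 1]])
    }, numeric(1))
    dia <- vapply(seq_len(nv - 1), function(j) {
      min(segment$abp[al$valleys[j]:al$valleys[j + 1]])
    }, numeric(1))
  }
  structure(
    list(
      r_peaks = r, ppg_peaks = pl$peaks, ppg_valleys = pl$valleys,
      abp_peaks = al$peaks, abp_valleys = al$valleys,
      abp_systolic = sys, abp_diastolic = dia
    ),
    class = "beat_annotations"
  )
}

#' Segment quality control
#'
#' A segment fails when, on any channel, (i) more than three consecutive
#' samples equal that channel's segment minimum or maximum (saturation),
#' (ii) any constant run lasts longer than one second (flatline), or (iii)
#' fewer than three beats were detected. Both count rules are strict
#' inequalities: exactly three extreme samples, or a constant run of exactly
#' one second, still passes. The verdict enumerates every rule that fired
#' as `"<rule>:<channel>"` reason codes.
#'
#' @param segment A [waveform_segment()].
#' @param annotations Matching [annotate_segment()] output.
#' @return `list(pass, reasons)`.
#' @export
qc_segment <- function(segment, annotations) {
  stopifnot(inherits(segment, "waveform_segment"))
  reasons <- character(0)
  fs <- segment$fs
  npeaks <- list(
    ecg = length(annotations$r_peaks),
    ppg = length(annotations$ppg_peaks),
    abp = length(annotations$abp_peaks)
  )
  for (ch in c("ecg", "ppg", "abp")) {
    x <- segment[[ch]]
    r <- rle(x)
    at_extreme <- r$values == min(x) | r$values == max(x)
    if (any(r$lengths > 3 & at_extreme)) {
      reasons <- c(reasons, paste0("saturation:", ch))
    }
    if (any(r$lengths > fs)) {
      reasons <- c(reasons, paste0("flatline:", ch))
    }
    if (npeaks[[ch]] < 3) {
      reasons <- c(reasons, paste0("peaks:", ch))
    }
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Reference blood pressure of a segment
#'
#' The segment's reference SBP (DBP) is the arithmetic mean of the per-beat
#' ABP maxima (minima).
#'
#' @param abp ABP sample series, mm Hg (retained in the signature for
#'   symmetry; the per-beat extremes are taken from `annotations`).
#' @param annotations [annotate_segment()] output with at least 3 beats.
#' @return `list(sbp, dbp)` in mm Hg.
#' @export
reference_bp <- function(abp, annotations) {
  if (length(annotations$abp_systolic) < 3) {
    stop(
      "fewer than 3 ABP beats; segment should have been removed by QC"
    )
  }
  sbp <- mean(annotations$abp_systolic)
  dbp <- mean(annotations$abp_diastolic)
  if (!(sbp > dbp)) stop("reference SBP must exceed reference DBP")
  list(sbp = sbp, dbp = dbp)
}
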
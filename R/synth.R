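#' Specification of a synthetic subject cohort
#'
#' Describes a cohort of synthetic subjects: its size, the fractions of
#' subjects falling into the blood-pressure categories used by the AAMI
#' cohort-composition criteria, the probability of a hemodynamic drift event,
#' and the master seed. Category fractions are honoured exactly (largest
#' remainder apportionment), so a cohort built from this specification meets
#' its requested composition at any size up to per-subject measurement noise.
#'
#' The defaults target an AAMI-compliant test cohort with margin above the
#' standard's minima (at least 5\% of subjects with SBP < 100, SBP > 160,
#' DBP < 60 and DBP > 100 mm Hg; at least 20\% with SBP > 140 and with
#' DBP > 85 mm Hg).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param sbp_mix Named fractions `c(lt100=, gt160=, gt140=)`; `gt140`
#'   includes `gt160`.
#' @param dbp_mix Named fractions `c(lt60=, gt100=, gt85=)`; `gt85` includes
#'   `gt100`.
#' @param drift_prob Probability that a subject carries one hemodynamic drift
#'   event: a vasomotor state change that shifts blood pressure and mean PPG
#'   level together while the pulse-arrival-time coupling re-equilibrates
#'   around the new state (so PAT does not encode the shift — the situation
#'   that makes re-calibration necessary).
#' @param spacing_s Nominal spacing between consecutive segments, seconds.
#' @param within_sbp_sd Step SD (mm Hg) of the within-subject slow SBP
#'   random walk, anchored at the subject's first segment. PAT tracks this
#'   walk through the subject's coupling.
#' @param pat_noise_ms Beat-to-beat pulse-arrival-time noise SD, ms.
#' @param seed Master seed for the cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        sbp_mix = c(lt100 = 0.10, gt160 = 0.10, gt140 = 0.25),
                        dbp_mix = c(lt60 = 0.10, gt100 = 0.10, gt85 = 0.25),
                        drift_prob = 0.4,
                        spacing_s = 540,
                        within_sbp_sd = 5,
                        pat_noise_ms = 2,
                        seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  for (mx in list(sbp_mix, dbp_mix)) {
    if (any(mx < 0 | mx > 1)) stop("category fractions must lie in [0, 1]")
  }
  if (sbp_mix[["gt140"]] < sbp_mix[["gt160"]]) {
    stop("sbp_mix: gt140 must include gt160 (gt140 >= gt160)")
  }
  if (dbp_mix[["gt85"]] < dbp_mix[["gt100"]]) {
    stop("dbp_mix: gt85 must include gt100 (gt85 >= gt100)")
  }
  if (sbp_mix[["lt100"]] + sbp_mix[["gt140"]] > 1) {
    stop("sbp_mix: exclusive categories sum to more than 1")
  }
  if (dbp_mix[["lt60"]] + dbp_mix[["gt85"]] > 1) {
    stop("dbp_mix: exclusive categories sum to more than 1")
  }
  if (drift_prob < 0 || drift_prob > 1) stop("drift_prob must lie in [0, 1]")
  structure(
    list(
      n_subjects = as.integer(n_subjects), sbp_mix = sbp_mix,
      dbp_mix = dbp_mix, drift_prob = drift_prob, spacing_s = spacing_s,
      within_sbp_sd = within_sbp_sd, pat_noise_ms = pat_noise_ms,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# cohort-level category labels, severity-aligned between SBP and DBP so that
# hypotensive SBP subjects are never assigned hypertensive DBP (and the
# invariant SBP > DBP holds with margin)
cohort_categories <- function(spec) {
  n <- spec$n_subjects
  sbp_counts <- apportion(n, c(
    gt160 = spec$sbp_mix[["gt160"]],
    mid140 = spec$sbp_mix[["gt140"]] - spec$sbp_mix[["gt160"]],
    normal = 1 - spec$sbp_mix[["gt140"]] - spec$sbp_mix[["lt100"]],
    lt100 = spec$sbp_mix[["lt100"]]
  ))
  dbp_counts <- apportion(n, c(
    gt100 = spec$dbp_mix[["gt100"]],
    mid85 = spec$dbp_mix[["gt85"]] - spec$dbp_mix[["gt100"]],
    normal = 1 - spec$dbp_mix[["gt85"]] - spec$dbp_mix[["lt60"]],
    lt60 = spec$dbp_mix[["lt60"]]
  ))
  sbp_lab <- rep(c("gt160", "mid140", "normal", "lt100"), sbp_counts)
  dbp_lab <- rep(c("gt100", "mid85", "normal", "lt60"), dbp_counts)
  perm <- with_seed(derive_seed(spec$seed, 7401), sample.int(n))
  list(sbp = sbp_lab[order(perm)], dbp = dbp_lab[order(perm)])
}

#' Draw one synthetic subject profile
#'
#' Generates the stable physiology of one subject: demographics, baseline
#' SBP/DBP/heart rate, the subject-specific coupling between blood pressure
#' and pulse arrival time (negative: higher pressure, earlier pulse arrival),
#' the coupling between blood pressure and PPG pulse amplitude, and an
#' optional hemodynamic drift event (a step change in BP accompanied by a
#' proportional shift in mean PPG level, placed early in the segment sequence
#' so that it falls inside the personalization pairing window).
#'
#' @param spec A [cohort_spec()].
#' @param index Subject position in the cohort (1-based, <= `n_subjects`).
#' @param rng_seed Optional explicit seed; defaults to a seed derived from
#'   the cohort seed and `index`.
#' @param n_segments Number of segments the subject will be rendered with
#'   (used to place the drift event).
#' @return An object of class `subject_profile`.
#' @export
make_subject <- function(spec, index, rng_seed = NULL, n_segments = 7) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (index < 1 || index > spec$n_subjects) {
    stop("index must lie in [1, n_subjects]")
  }
  cats <- cohort_categories(spec)
  seed <- rng_seed %||% derive_seed(spec$seed, index)
  with_seed(seed, {
    sbp <- switch(cats$sbp[index],
      lt100 = runif(1, 85, 98),
      normal = runif(1, 102, 138),
      mid140 = runif(1, 142, 160),
      gt160 = runif(1, 162, 190)
    )
    dbp <- switch(cats$dbp[index],
      lt60 = runif(1, 45, 58),
      normal = runif(1, 62, 84),
      mid85 = runif(1, 86, 100),
      gt100 = runif(1, 101, 112)
    )
    dbp <- min(dbp, sbp - 20)
    age <- if (runif(1) < 0.88) sample(41:90, 1) else sample(18:40, 1)
    sex <- rbinom(1, 1, 0.42) # 1 = female
    hr <- runif(1, 55, 95)
    pat0 <- rnorm(1, 235, 2) # ms; tight spread, so PAT deviations are
    # informative about within-subject BP deviations
    pat_coupling <- runif(1, -1.1, -0.7) # mm Hg per ms
    amp_coupling <- runif(1, 0.002, 0.006) # relative amplitude per mm Hg
    ppg_dc <- runif(1, 0.8, 1.2)
    ppg_amp <- runif(1, 0.3, 0.6)
    drift <- NULL
    if (runif(1) < spec$drift_prob && n_segments >= 2) {
      d_sbp <- sample(c(-1, 1), 1) * runif(1, 12, 30)
      drift <- data.frame(
        segment_index = sample(2:max(2, min(3, n_segments)), 1),
        ppg_shift = 0.006 * d_sbp,
        sbp_shift = d_sbp,
        dbp_shift = 0.6 * d_sbp
      )
    }
    structure(
      list(
        subject_id = sprintf("S%04d", index), age = as.integer(age),
        sex = as.integer(sex), baseline_sbp = sbp, baseline_dbp = dbp,
        baseline_hr = hr, pat0_ms = pat0, pat_coupling = pat_coupling,
        amp_coupling = amp_coupling, ppg_dc = ppg_dc, ppg_amp = ppg_amp,
        drift_schedule = drift, spacing_s = spec$spacing_s,
        within_sbp_sd = spec$within_sbp_sd,
        pat_noise_ms = spec$pat_noise_ms, seed = seed
      ),
      class = "subject_profile"
    )
  })
}

# asymmetric gamma-like pulse on phase u in [0, 1); peak value 1 at u = upk
pulse_shape <- function(u, upk) {
  k <- 3
  theta <- upk / k
  g <- (u / upk)^k * exp((upk - u) / theta)
  g[u < 0] <- 0
  g
}

#' Render one synthetic 3-channel waveform segment
#'
#' Produces synchronized ECG, PPG and ABP series for one 10-second segment of
#' a subject. The ECG is a train of Gaussian QRS bumps with baseline wander
#' and noise; each PPG pulse starts (pulse foot / diastolic valley) one pulse
#' arrival time after its R peak, with the PAT and pulse amplitude modulated
#' by the segment's instantaneous blood pressure through the subject's
#' couplings; the ABP channel is a pulse train whose per-beat extremes equal
#' the per-beat systolic/diastolic pressures. Ground-truth beat landmarks and
#' per-beat pressures are attached as annotations. A drift event scheduled at
#' or before this segment shifts both the mean PPG level and the blood
#' pressure from that segment onward.
#'
#' @param profile A [make_subject()] profile.
#' @param segment_index 1-based segment position in the subject's sequence.
#' @param duration_s Segment duration in seconds (default 10).
#' @param fs Sampling rate in Hz (default 125).
#' @return A [waveform_segment()] with ground-truth annotations.
#' @export
render_segment <- function(profile, segment_index, duration_s = 10,
                           fs = 125) {
  stopifnot(inherits(profile, "subject_profile"))
  if (duration_s <= 0 || fs <= 0) stop("duration_s and fs must be positive")
  n <- duration_s * fs
  if (abs(n - round(n)) > 1e-9) stop("duration_s * fs must be an integer")
  n <- as.integer(round(n))
  with_seed(derive_seed(profile$seed, 911, segment_index), {
    drift_sbp <- 0
    drift_dbp <- 0
    drift_ppg <- 0
    ds <- profile$drift_schedule
    if (!is.null(ds) && segment_index >= ds$segment_index[1]) {
      drift_sbp <- ds$sbp_shift[1]
      drift_dbp <- ds$dbp_shift[1]
      drift_ppg <- ds$ppg_shift[1]
    }
    # within-subject slow random walk, anchored at segment 1; PAT tracks
    # the walk but not the drift jump (vasomotor re-equilibration)
    walk <- 0
    if (segment_index >= 2) {
      steps <- vapply(2:segment_index, function(j) {
        with_seed(derive_seed(profile$seed, 313, j), rnorm(1))
      }, numeric(1))
      walk <- sum(steps) * profile$within_sbp_sd
    }
    sbp_seg <- profile$baseline_sbp + walk + drift_sbp
    dbp_seg <- profile$baseline_dbp + 0.6 * walk + drift_dbp
    hr_seg <- profile$baseline_hr + rnorm(1, 0, 2)

    # beat schedule; a lead-in beat before t=0 and one beyond the end keep
    # the pulse channels beat-covered across the whole window
    period <- 60 / hr_seg
    r_times <- seq(0.25 - period, duration_s + period, by = period)
    r_times <- r_times + rnorm(length(r_times), 0, 0.01)
    nb <- length(r_times)

    sbp_beat <- sbp_seg + rnorm(nb, 0, 1)
    dbp_beat <- dbp_seg + rnorm(nb, 0, 0.7)
    dbp_beat <- pmin(dbp_beat, sbp_beat - 10)
    tracked_dev <- sbp_beat - drift_sbp - profile$baseline_sbp
    pat_ms <- profile$pat0_ms + tracked_dev / profile$pat_coupling +
      rnorm(nb, 0, profile$pat_noise_ms)
    pat_ms <- pmax(pat_ms, 80)

    t <- (seq_len(n) - 1) / fs

    # ECG: Gaussian QRS bumps + wander + noise
    ecg <- 0.05 * sin(2 * pi * 0.3 * t + runif(1, 0, 2 * pi)) +
      rnorm(n, 0, 0.02)
    for (k in seq_len(nb)) {
      ecg <- ecg + exp(-0.5 * ((t - r_times[k]) / 0.012)^2)
    }

    # PPG: pulse per beat from its foot (R time + PAT) to the next foot
    dc <- profile$ppg_dc * (1 + drift_ppg) * (1 + rnorm(1, 0, 0.004))
    amp_beat <- profile$ppg_amp * (1 + profile$amp_coupling * tracked_dev)
    amp_beat <- pmax(amp_beat, 0.05)
    onset <- r_times + pat_ms / 1000
    ppg <- rep(dc, n)
    abp_onset <- r_times + 0.15
    abp <- rep(dbp_beat[1], n)
    ppg_peak_idx <- rep(NA_integer_, nb)
    for (k in seq_len(nb)) {
      o <- onset[k]
      o_next <- if (k < nb) onset[k + 1] else o + period
      idx <- which(t >= o & t < o_next)
      if (length(idx)) {
        u <- (t[idx] - o) / (o_next - o)
        ppg[idx] <- dc + amp_beat[k] * pulse_shape(u, 0.30)
        pk <- idx[which.max(ppg[idx])]
        if (pk > 1 && pk < n) ppg_peak_idx[k] <- pk
      }
      a <- abp_onset[k]
      a_next <- if (k < nb) abp_onset[k + 1] else a + period
      aidx <- which(t >= a & t < a_next)
      if (length(aidx)) {
        ua <- (t[aidx] - a) / (a_next - a)
        abp[aidx] <- dbp_beat[k] +
          (sbp_beat[k] - dbp_beat[k]) * pulse_shape(ua, 0.25)
      }
    }
    abp[t < abp_onset[1]] <- dbp_beat[1]
    ppg[t < onset[1]] <- dc
    ppg <- ppg + rnorm(n, 0, 0.004)

    inside <- which(r_times > 0 & r_times <= duration_s - 1 / fs)
    r_idx <- round(r_times[inside] * fs) + 1L
    v_idx <- round(onset[inside] * fs) + 1L
    keepv <- v_idx <= n
    ann <- list(
      r_peaks = r_idx,
      ppg_valleys = v_idx[keepv],
      ppg_peaks = ppg_peak_idx[inside][keepv],
      pat_ms = pat_ms[inside][keepv],
      sbp = sbp_beat[inside],
      dbp = dbp_beat[inside],
      segment_sbp = sbp_seg,
      segment_dbp = dbp_seg
    )
    waveform_segment(
      subject_id = profile$subject_id,
      t0 = (segment_index - 1) * profile$spacing_s,
      fs = fs, ecg = ecg, ppg = ppg, abp = abp,
      annotations = ann, age = profile$age, sex = profile$sex
    )
  })
}

#' Generate a full synthetic dataset
#'
#' Draws `n_subjects` profiles from the cohort specification and renders
#' `segments_per_subject` consecutive segments for each, in temporal order.
#' Fully reproducible from `spec$seed` (or the `seed` override).
#'
#' @param spec A [cohort_spec()].
#' @param segments_per_subject Number of segments per subject (>= 1).
#' @param seed Optional override of `spec$seed`.
#' @param duration_s,fs Segment duration and sampling rate.
#' @return A named list, one entry per subject:
#'   `list(profile, subject_id, age, sex, segments)`.
#' @export
make_dataset <- function(spec, segments_per_subject, seed = NULL,
                         duration_s = 10, fs = 125) {
  if (segments_per_subject < 1) stop("segments_per_subject must be >= 1")
  if (!is.null(seed)) {
    spec$seed <- as.integer(seed)
  }
  out <- lapply(seq_len(spec$n_subjects), function(i) {
    prof <- make_subject(spec, i, n_segments = segments_per_subject)
    segs <- lapply(seq_len(segments_per_subject), function(k) {
      render_segment(prof, k, duration_s = duration_s, fs = fs)
    })
    list(
      profile = prof, subject_id = prof$subject_id, age = prof$age,
      sex = prof$sex, segments = segs
    )
  })
  names(out) <- vapply(out, `[[`, character(1), "subject_id")
  out
}

#' Tabulate the segment plan of a dataset without rendering waveforms
#'
#' Returns the (subject, segment index, start time) table that
#' [make_dataset()] would realize, without generating any samples. Useful to
#' reason about dataset sizes at full study scale.
#'
#' @inheritParams make_dataset
#' @return A data.frame with columns `subject_id`, `segment_index`, `t0`.
#' @export
dataset_plan <- function(spec, segments_per_subject) {
  if (segments_per_subject < 1) stop("segments_per_subject must be >= 1")
  data.frame(
    subject_id = rep(sprintf("S%04d", seq_len(spec$n_subjects)),
                     each = segments_per_subject),
    segment_index = rep(seq_len(segments_per_subject), spec$n_subjects),
    t0 = rep((seq_len(segments_per_subject) - 1) * spec$spacing_s,
             spec$n_subjects)
  )
}

#' Inject a constant-valued artifact into one channel
#'
#' Overwrites a time window of one channel with a constant, emulating sensor
#' saturation or a flatline; used to exercise the segment quality-control
#' rules.
#'
#' @param segment A [waveform_segment()].
#' @param channel One of `"ecg"`, `"ppg"`, `"abp"`.
#' @param start_s,duration_s Window start and length in seconds.
#' @param value Constant to write; defaults to the channel minimum.
#' @return The modified segment.
#' @export
inject_flatline <- function(segment, channel = c("ppg", "ecg", "abp"),
                            start_s, duration_s, value = NULL) {
  channel <- match.arg(channel)
  x <- segment[[channel]]
  fs <- segment$fs
  idx <- seq(floor(start_s * fs) + 1, min(length(x),
                                          floor((start_s + duration_s) * fs)))
  x[idx] <- value %||% min(x)
  segment[[channel]] <- x
  segment
}
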
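test_that("R-peak detection recovers known peaks and rejects degenerate input", {
  tr <- fix_segment$annotations$r_peaks
  det <- detect_r_peaks(fix_segment$ecg, fix_segment$fs)
  hits <- vapply(det, function(p) any(abs(tr - p) <= 2), logical(1))
  expect_true(all(hits))
  expect_gte(sum(hits), length(tr) - 1) # the warm-up beat may be missed

  expect_length(detect_r_peaks(rep(0, 1250), 125), 0)
  expect_warning(out <- detect_r_peaks(rnorm(100), 125), "shorter")
  expect_length(out, 0)

  # single clean QRS template at a known index
  t <- (0:1249) / 125
  one <- exp(-0.5 * ((t - 5) / 0.012)^2)
  det1 <- detect_r_peaks(one, 125)
  expect_length(det1, 1)
  expect_lt(abs(det1 - 626), 3)
})

test_that("PPG landmark detection finds peaks and the valleys between them", {
  tp <- fix_segment$annotations$ppg_peaks
  tv <- fix_segment$annotations$ppg_valleys
  lm <- detect_ppg_landmarks(fix_segment$ppg, fix_segment$fs)
  hit_p <- vapply(lm$peaks, function(p) any(abs(tp - p) <= 3, na.rm = TRUE),
                  logical(1))
  expect_gte(mean(hit_p), 0.9)
  # the decay tail is nearly flat approaching the pulse foot, so the
  # detected minimum may sit a few samples before the annotated onset
  hit_v <- vapply(lm$valleys, function(p) any(abs(tv - p) <= 5),
                  logical(1))
  expect_gte(mean(hit_v), 0.9)
  # exactly one valley between consecutive peaks, below both
  expect_equal(length(lm$valleys), length(lm$peaks) - 1)
  for (j in seq_along(lm$valleys)) {
    expect_true(lm$valleys[j] > lm$peaks[j] &&
                  lm$valleys[j] < lm$peaks[j + 1])
    expect_lte(fix_segment$ppg[lm$valleys[j]],
               min(fix_segment$ppg[lm$peaks[j:(j + 1)]]))
  }

  # strictly monotone ramp: no pulsatile structure
  ramp <- detect_ppg_landmarks(seq(0, 1, length.out = 1250), 125)
  expect_length(ramp$peaks, 0)
  expect_length(ramp$valleys, 0)
})

test_that("beat recall and precision stay high across random segments", {
  spec <- cohort_spec(25, seed = 606)
  tot <- c(tp_r = 0, det_r = 0, true_r = 0, tp_p = 0, det_p = 0,
           true_p = 0)
  for (i in 1:25) {
    prof <- make_subject(spec, i)
    for (k in c(2, 5)) {
      seg <- render_segment(prof, k)
      ann <- annotate_segment(seg)
      tr <- seg$annotations$r_peaks
      hit <- vapply(ann$r_peaks, function(p) any(abs(tr - p) <= 3),
                    logical(1))
      tot["tp_r"] <- tot["tp_r"] + sum(hit)
      tot["det_r"] <- tot["det_r"] + length(hit)
      tot["true_r"] <- tot["true_r"] + length(tr)
      tp <- seg$annotations$ppg_peaks
      hit_p <- vapply(ann$ppg_peaks,
                      function(p) any(abs(tp - p) <= 3, na.rm = TRUE),
                      logical(1))
      tot["tp_p"] <- tot["tp_p"] + sum(hit_p)
      tot["det_p"] <- tot["det_p"] + length(hit_p)
      tot["true_p"] <- tot["true_p"] + sum(!is.na(tp))
    }
  }
  expect_gte(tot["tp_r"] / tot["det_r"], 0.95) # precision
  expect_gte(tot["tp_r"] / tot["true_r"], 0.95) # recall
  expect_gte(tot["tp_p"] / tot["det_p"], 0.95)
  expect_gte(tot["tp_p"] / tot["true_p"], 0.95)
})

test_that("QC rules fire exactly as specified", {
  clean <- qc_segment(fix_segment, fix_ann)
  expect_true(clean$pass)

  flat <- inject_flatline(fix_segment, "ppg", 3, 2)
  qc1 <- qc_segment(flat, fix_ann)
  expect_false(qc1$pass)
  expect_true("flatline:ppg" %in% qc1$reasons)

  # exactly 3 consecutive samples at the channel maximum still passes
  # the saturation rule (the rule is "more than three")
  seg3 <- fix_segment
  mx <- max(seg3$ecg)
  run <- which.max(seg3$ecg)
  seg3$ecg[run + c(-1, 0, 1)] <- mx + 0.5
  qc3 <- qc_segment(seg3, fix_ann)
  expect_false("saturation:ecg" %in% qc3$reasons)
  # a fourth sample tips it over
  seg4 <- seg3
  seg4$ecg[run + 2] <- mx + 0.5
  expect_true("saturation:ecg" %in% qc_segment(seg4, fix_ann)$reasons)

  # fewer than 3 detected beats on any channel fails that channel
  few <- fix_ann
  few$abp_peaks <- few$abp_peaks[1:2]
  expect_true("peaks:abp" %in% qc_segment(fix_segment, few)$reasons)

  # pure function: same verdict on repeated calls
  expect_identical(qc_segment(flat, fix_ann), qc_segment(flat, fix_ann))
})

test_that("reference BP is the mean of per-beat extremes", {
  ann <- fix_ann
  ann$abp_systolic <- c(120, 122, 118)
  ann$abp_diastolic <- c(78, 80, 82)
  rb <- reference_bp(NULL, ann)
  expect_equal(rb$sbp, 120)
  expect_equal(rb$dbp, 80)

  ann$abp_systolic <- rep(110, 5)
  ann$abp_diastolic <- rep(70, 5)
  rb2 <- reference_bp(NULL, ann)
  expect_equal(rb2$sbp, 110)
  expect_equal(rb2$dbp, 70)

  ann$abp_systolic <- c(120, 118)
  expect_error(reference_bp(NULL, ann), "QC")

  # against the generator's per-beat ground truth
  rb3 <- reference_bp(fix_segment$abp, fix_ann)
  expect_lt(abs(rb3$sbp - mean(fix_segment$annotations$sbp)), 0.5)
  expect_lt(abs(rb3$dbp - mean(fix_segment$annotations$dbp)), 0.5)
})
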
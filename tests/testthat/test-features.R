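test_that("temporal features follow the stated arithmetic", {
  seg <- waveform_segment("T", 0, 125, rep(0, 500), rep(0, 500),
                          rep(0, 500))
  ann <- list(
    r_peaks = c(1L, 101L, 201L, 301L),
    ppg_valleys = c(26L, 126L, 226L, 326L)
  )
  tf <- temporal_features(seg, ann)
  expect_equal(tf$heart_rate, 75) # R-R = 0.8 s
  expect_equal(tf$pat, 0.2) # 25 samples at 125 Hz

  expect_error(
    temporal_features(seg, list(r_peaks = c(1L, 2L), ppg_valleys = 5L)),
    ">= 4 R peaks"
  )
})

test_that("morphology features reproduce triangular-pulse geometry", {
  tri <- triangle_segment(amp = 1)
  mf <- morphology_features(tri$segment, tri$ann, seed = 3)
  expect_equal(mf$t_valley_to_peak, 0.3, tolerance = 0.02)
  expect_equal(mf$t_peak_to_next_valley, 0.5, tolerance = 0.02)
  expect_equal(mf$ppg_peak_amplitude, 1.0, tolerance = 1e-9)
  expect_equal(mf$ppg_upslope, 1 / 0.3, tolerance = 0.05)

  # doubling the amplitude doubles amplitude and upslope, not the times
  tri2 <- triangle_segment(amp = 2)
  mf2 <- morphology_features(tri2$segment, tri2$ann, seed = 3)
  expect_equal(mf2$ppg_peak_amplitude, 2 * mf$ppg_peak_amplitude)
  expect_equal(mf2$ppg_upslope, 2 * mf$ppg_upslope)
  expect_equal(mf2$t_valley_to_peak, mf$t_valley_to_peak)

  # seeded beat-triple selection is reproducible
  expect_identical(
    morphology_features(fix_segment, fix_ann, seed = 12),
    morphology_features(fix_segment, fix_ann, seed = 12)
  )

  short <- tri$ann
  short$ppg_valleys <- short$ppg_valleys[1:3]
  short$ppg_peaks <- short$ppg_peaks[1:2]
  expect_error(morphology_features(tri$segment, short, seed = 1),
               ">= 4")
})

test_that("examples carry the mode-dependent slot counts", {
  ex32 <- build_example(fix_segment, fix_ann, mode = "calibration_free")
  expect_length(ex32$features, 32)
  expect_identical(names(ex32$features),
                   feature_column_order("calibration_free"))

  cal <- list(mean = 95, sd = 12, t0 = -540)
  ex34 <- build_example(fix_segment, fix_ann,
    mode = "personalized", cal_abp = cal
  )
  expect_length(ex34$features, 34)
  expect_equal(ex34$features[["cal_abp_mean"]], 95)

  # calibration from the same (or a later) segment is a protocol violation
  expect_error(
    build_example(fix_segment, fix_ann,
      mode = "personalized",
      cal_abp = list(mean = 95, sd = 12, t0 = fix_segment$t0)
    ),
    "protocol violation"
  )
  expect_error(
    build_example(fix_segment, fix_ann, mode = "personalized"),
    "requires cal_abp"
  )
})

test_that("calibration-free features ignore the ABP channel contents", {
  seg2 <- fix_segment
  seg2$abp <- seg2$abp + 25
  ann2 <- annotate_segment(seg2)
  a <- build_example(fix_segment, fix_ann, mode = "calibration_free",
                     seed = 5)
  b <- build_example(seg2, ann2, mode = "calibration_free", seed = 5)
  expect_equal(a$features, b$features)
  # while the targets do track the reference channel
  expect_equal(b$target_sbp - a$target_sbp, 25, tolerance = 1e-6)
})

test_that("every QC-passing synthetic segment yields finite features", {
  spec <- cohort_spec(40, seed = 2024)
  n_checked <- 0
  for (i in 1:40) {
    prof <- make_subject(spec, i)
    for (k in c(1, 4)) {
      seg <- render_segment(prof, k)
      ann <- annotate_segment(seg)
      if (!qc_segment(seg, ann)$pass) next
      ex <- build_example(seg, ann, mode = "calibration_free",
                          seed = i * 10 + k)
      expect_true(all(is.finite(ex$features)))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 70)
})
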
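test_that("subject generation is deterministic and respects cohort mixes", {
  p1 <- make_subject(fix_spec, 3)
  p2 <- make_subject(fix_spec, 3)
  expect_identical(p1, p2)

  # degenerate mix: every baseline SBP below 100
  hypo <- cohort_spec(15,
    sbp_mix = c(lt100 = 1, gt160 = 0, gt140 = 0),
    dbp_mix = c(lt60 = 1, gt100 = 0, gt85 = 0), seed = 2
  )
  sbps <- vapply(1:15, function(i) make_subject(hypo, i)$baseline_sbp,
                 numeric(1))
  expect_true(all(sbps < 100))

  # invalid mixes are rejected
  expect_error(
    cohort_spec(10, sbp_mix = c(lt100 = 0.6, gt160 = 0.2, gt140 = 0.5)),
    "exclusive"
  )
})

test_that("cohort category fractions match the requested mixes at n=116", {
  # exact apportionment: count over several cohorts, each within 2 points
  for (s in 1:5) {
    spec <- cohort_spec(116, seed = s)
    profs <- lapply(1:116, function(i) make_subject(spec, i))
    sbp <- vapply(profs, `[[`, numeric(1), "baseline_sbp")
    dbp <- vapply(profs, `[[`, numeric(1), "baseline_dbp")
    expect_lt(abs(mean(sbp < 100) - 0.10), 0.02)
    expect_lt(abs(mean(sbp > 160) - 0.10), 0.02)
    expect_lt(abs(mean(sbp > 140) - 0.25), 0.02)
    expect_lt(abs(mean(dbp < 60) - 0.10), 0.02)
    expect_true(all(sbp > dbp))
  }
})

test_that("rendered segments carry the configured beat structure", {
  spec <- cohort_spec(3, drift_prob = 0, seed = 31)
  prof <- make_subject(spec, 1)
  prof$baseline_hr <- 75
  seg <- render_segment(prof, 1)
  # 75 bpm over 10 s: 12 or 13 annotated R peaks (edge beats may fall out)
  expect_true(length(seg$annotations$r_peaks) %in% c(12, 13))
  expect_equal(length(seg$ecg), 1250)

  # annotated PAT equals the R-peak -> PPG-valley lag within one sample
  lag_ms <- (seg$annotations$ppg_valleys -
    seg$annotations$r_peaks[seq_along(seg$annotations$ppg_valleys)]) /
    seg$fs * 1000
  expect_true(all(abs(lag_ms - seg$annotations$pat_ms) <= 1000 / seg$fs))

  expect_error(render_segment(prof, 1, duration_s = -1), "positive")
  expect_error(render_segment(prof, 1, duration_s = 10.3, fs = 125),
               "integer")
})

test_that("drift events shift mean PPG from the scheduled segment onward", {
  spec <- cohort_spec(3, drift_prob = 1, seed = 77)
  prof <- make_subject(spec, 2)
  prof$drift_schedule <- data.frame(
    segment_index = 3, ppg_shift = 0.10, sbp_shift = 16, dbp_shift = 9.6
  )
  m1 <- mean(render_segment(prof, 1)$ppg)
  m3 <- mean(render_segment(prof, 3)$ppg)
  expect_gte((m3 - m1) / m1, 0.05)
})

test_that("SBP and annotated PAT are negatively rank-correlated in-subject", {
  spec <- cohort_spec(4, drift_prob = 0, seed = 55)
  for (i in 1:3) {
    prof <- make_subject(spec, i, n_segments = 24)
    segs <- lapply(1:24, function(k) render_segment(prof, k))
    sbp <- vapply(segs, function(s) s$annotations$segment_sbp, numeric(1))
    pat <- vapply(segs, function(s) mean(s$annotations$pat_ms), numeric(1))
    expect_lt(cor(sbp, pat, method = "spearman"), 0)
  }
})

test_that("waveforms are finite and ABP beats keep systolic above diastolic", {
  for (subj in fix_dataset) {
    for (seg in subj$segments) {
      expect_true(all(is.finite(c(seg$ecg, seg$ppg, seg$abp))))
      expect_true(all(seg$annotations$sbp > seg$annotations$dbp))
    }
  }
})

test_that("datasets are reproducible and temporally ordered", {
  d1 <- make_dataset(cohort_spec(2, seed = 12), 7)
  d2 <- make_dataset(cohort_spec(2, seed = 12), 7)
  expect_identical(
    d1[[1]]$segments[[3]]$annotations, d2[[1]]$segments[[3]]$annotations
  )
  expect_identical(d1[[2]]$segments[[5]]$ppg, d2[[2]]$segments[[5]]$ppg)
  t0s <- vapply(d1[[1]]$segments, `[[`, numeric(1), "t0")
  expect_true(all(diff(t0s) > 0))
})

test_that("the dataset plan reproduces the full-study segment count", {
  plan <- dataset_plan(cohort_spec(1293, seed = 1), 19)
  expect_equal(nrow(plan), 24567)
  expect_equal(length(unique(plan$subject_id)), 1293)
})

test_that("generated test cohorts pass the AAMI cohort checker", {
  # per-subject reference BP from rendered segments, 6 seeds; the checker
  # must pass in at least 5 (design target: >= 95% of seeds)
  passes <- vapply(1:6, function(s) {
    spec <- cohort_spec(116, seed = 1000 + s)
    profs <- lapply(1:116, function(i) make_subject(spec, i))
    refs <- vapply(profs, function(p) {
      segs <- lapply(c(1, 4, 7), function(k) render_segment(p, k))
      sb <- db <- numeric(0)
      for (seg in segs) {
        ann <- annotate_segment(seg)
        rb <- reference_bp(seg$abp, ann)
        sb <- c(sb, rb$sbp)
        db <- c(db, rb$dbp)
      }
      c(mean(sb), mean(db))
    }, numeric(2))
    aami_cohort_check(refs[1, ], refs[2, ])$pass
  }, logical(1))
  expect_gte(sum(passes), 5)
})

test_that("inject_flatline overwrites the requested window", {
  seg <- inject_flatline(fix_segment, "ppg", 2, 1.5)
  idx <- (2 * 125 + 1):(3.5 * 125)
  expect_true(all(seg$ppg[idx] == min(fix_segment$ppg)))
  expect_identical(seg$ecg, fix_segment$ecg)
})
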
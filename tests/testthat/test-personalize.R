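# brute-force oracle: enumerate the protocol rule directly
oracle_plan <- function(m, threshold = 0.05) {
  out <- list()
  for (i in 1:3) {
    a <- i + 1
    b <- i + 4
    dev <- abs(m[a] - m[1]) / abs(m[1])
    out[[i]] <- if (dev <= threshold) {
      c(test = a, cal = 1, recal = 0)
    } else {
      c(test = b, cal = a, recal = 1)
    }
  }
  do.call(rbind, out)
}

test_that("plan_pairs equals exhaustive enumeration on all deviation patterns", {
  set.seed(99)
  for (pattern in 0:7) {
    dev_flags <- as.logical(bitwAnd(pattern, c(1, 2, 4)))
    for (rep in 1:12) {
      base <- runif(1, 0.5, 2)
      m <- rep(base, 7)
      m[2:4] <- base * (1 + ifelse(dev_flags,
        sample(c(-1, 1), 3, TRUE) * runif(3, 0.06, 0.30),
        runif(3, -0.04, 0.04)
      ))
      m[5:7] <- base * (1 + runif(3, -0.3, 0.3))
      plan <- plan_pairs(m, threshold = 0.05)
      orc <- oracle_plan(m, 0.05)
      expect_equal(plan$assignments$test, unname(orc[, "test"]))
      expect_equal(plan$assignments$cal, unname(orc[, "cal"]))
      expect_equal(plan$assignments$recalibrated,
                   as.logical(orc[, "recal"]))
      expect_equal(nrow(plan$assignments), 3)
      # no segment is both tested and used as calibration
      expect_length(
        intersect(plan$assignments$test, plan$assignments$cal), 0
      )
    }
  }
})

test_that("the worked pairing examples hold", {
  # all means equal: default calibration from segment 1 throughout
  p <- plan_pairs(rep(1, 7))
  expect_equal(p$assignments$test, c(2, 3, 4))
  expect_equal(p$assignments$cal, c(1, 1, 1))
  expect_false(any(p$assignments$recalibrated))
  expect_equal(sort(p$unused), c(5, 6, 7))

  # segment 2 deviates by 10%: its reserve is tested instead
  m <- rep(1, 7)
  m[2] <- 1.10
  p2 <- plan_pairs(m)
  expect_equal(p2$assignments$test, c(5, 3, 4))
  expect_equal(p2$assignments$cal, c(2, 1, 1))
  expect_equal(sum(p2$assignments$recalibrated), 1)

  # all three early segments deviate: full re-calibration
  m3 <- c(1, 1.2, 0.8, 1.3, 1, 1, 1)
  p3 <- plan_pairs(m3)
  expect_equal(p3$assignments$test, c(5, 6, 7))
  expect_equal(p3$assignments$cal, c(2, 3, 4))
  expect_equal(sum(p3$assignments$recalibrated), 3)

  expect_warning(out <- plan_pairs(rep(1, 5)), "excluded")
  expect_null(out)
  expect_error(plan_pairs(c(0, rep(1, 6))), "undefined")
})

test_that("plan_pairs validates temporal order of real segments", {
  segs <- fix_dataset[[1]]$segments
  segs7 <- c(segs, segs, segs)[1:7]
  expect_error(plan_pairs(segs7), "ascending")
})

test_that("recalibration_rate counts subjects, not assignments", {
  none <- plan_pairs(rep(1, 7))
  all3 <- plan_pairs(c(1, 1.2, 0.8, 1.3, 1, 1, 1))
  one <- plan_pairs(c(1, 1.1, 1, 1, 1, 1, 1))
  expect_equal(recalibration_rate(list(none, none)), 0)
  expect_equal(recalibration_rate(list(all3, one)), 1)
  expect_equal(recalibration_rate(list(none, all3, one, none)), 0.5)
  expect_error(recalibration_rate(list()), "no pairing plans")
})

test_that("drift injection drives the re-calibration rate to the drift rate", {
  spec <- cohort_spec(150, drift_prob = 0.4, seed = 3110)
  predicted <- 0
  plans <- lapply(1:150, function(i) {
    prof <- make_subject(spec, i, n_segments = 7)
    ds <- prof$drift_schedule
    if (!is.null(ds) && abs(ds$ppg_shift[1]) > 0.05) {
      predicted <<- predicted + 1
    }
    m <- vapply(1:7, function(k) mean(render_segment(prof, k)$ppg),
                numeric(1))
    plan_pairs(m, threshold = 0.05)
  })
  rate <- recalibration_rate(plans)
  # matches the generator's ground truth (drift shifts beyond threshold) ...
  expect_lt(abs(rate - predicted / 150), 0.05)
  # ... and sits near the injected 40% drift rate
  expect_lt(abs(rate - 0.40), 0.07)
})
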
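test_that("error summaries reproduce hand-computed statistics", {
  s <- error_summary(c(121, 118, 125), c(120, 120, 120))
  expect_equal(s$me, 4 / 3)
  expect_equal(s$mae, 8 / 3)
  expect_equal(
    s$sd,
    sqrt(((1 - 4 / 3)^2 + (-2 - 4 / 3)^2 + (5 - 4 / 3)^2) / 2)
  )
  expect_equal(s$residuals, c(1, -2, 5))

  ident <- error_summary(c(110, 120), c(110, 120))
  expect_equal(ident$me, 0)
  expect_equal(ident$sd, 0)
  expect_equal(ident$mae, 0)

  sym <- error_summary(c(114, 126), c(120, 120))
  expect_equal(sym$me, 0)
  expect_equal(sym$mae, 6)

  expect_error(error_summary(1:3, 1:4), "equal length")
  expect_error(error_summary(120, 118), "n >= 2")
})

test_that("summary invariants hold on random pairs", {
  set.seed(71)
  for (i in 1:200) {
    n <- sample(3:50, 1)
    est <- rnorm(n, 120, 15)
    ref <- rnorm(n, 120, 15)
    s <- error_summary(est, ref)
    expect_gte(s$mae, abs(s$me))
    expect_false(is.unsorted(s$pct_within))
    shift <- runif(1, -30, 30)
    expect_equal(error_summary(est + shift, ref + shift)$sd, s$sd)
  }
})

test_that("AAMI device verdicts match the reported pass/fail pattern", {
  mk <- function(me, sd, n = 348) {
    # synthesize residuals with exactly the requested mean and SD
    r <- scale(rnorm(n))[, 1] * sd + me
    error_summary(r, rep(0, n))
  }
  both <- aami_device_check(mk(-1.31, 7.91))
  expect_true(both$bias_pass && both$sd_pass)
  sd_fail <- aami_device_check(mk(-1.86, 19.55))
  expect_true(sd_fail$bias_pass)
  expect_false(sd_fail$sd_pass)
  zero <- aami_device_check(mk(0, 0.0001))
  expect_true(zero$bias_pass && zero$sd_pass)
})

test_that("BHS grading reproduces the published thresholds", {
  expect_equal(bhs_grade(c(0.658, 0.917, 0.950)), "A")
  expect_equal(bhs_grade(c(0.50, 0.75, 0.90)), "B") # boundaries inclusive
  expect_equal(bhs_grade(c(0.60, 0.85, 0.95)), "A")
  expect_equal(bhs_grade(c(0.40, 0.65, 0.80)), "C")
  expect_equal(bhs_grade(c(0, 0, 0)), "D")
  expect_equal(bhs_grade(c(0.59, 0.99, 1)), "B") # all three must hold
  expect_error(bhs_grade(c(0.9, 0.8, 0.95)), "non-decreasing")

  # monotonicity: improving any fraction never lowers the grade
  set.seed(5)
  grades <- c(D = 0, C = 1, B = 2, A = 3)
  for (i in 1:100) {
    p <- sort(runif(3))
    q <- pmin(p + c(0, 0, runif(1, 0, 0.3))[sample(3)], 1)
    q <- sort(pmax(p, q))
    expect_gte(grades[bhs_grade(q)], grades[bhs_grade(p)])
  }
})

test_that("the cohort checker applies all composition criteria", {
  set.seed(31)
  n <- 116
  sbp <- c(rep(92, 12), rep(170, 12), rep(150, 17), runif(75, 105, 138))
  dbp <- pmin(c(rep(50, 12), rep(105, 12), rep(92, 17),
                runif(75, 62, 84)), sbp - 20)
  full <- aami_cohort_check(sbp, dbp)
  expect_true(full$pass)

  small <- aami_cohort_check(sbp[1:84], dbp[1:84])
  expect_false(small$pass)
  expect_false(small$detail$pass[small$detail$criterion == "n_subjects"])

  flat <- aami_cohort_check(rep(120, 116), rep(80, 116))
  expect_false(flat$pass)
  expect_equal(sum(flat$detail$pass), 1) # only the size criterion holds
})

test_that("Bland-Altman limits follow the difference distribution", {
  ba0 <- bland_altman(c(120, 130), c(120, 130))
  expect_true(all(ba0$difference == 0))
  expect_equal(attr(ba0, "lower"), 0)

  ba <- bland_altman(c(114, 126), c(120, 120))
  expect_equal(attr(ba, "upper"), 2 * sd(c(-6, 6)), tolerance = 1e-12)
  expect_equal(attr(ba, "upper"), 16.97, tolerance = 0.01)
  expect_equal(nrow(ba), 2)

  set.seed(8)
  est <- rnorm(40, 120, 10)
  ref <- rnorm(40, 120, 10)
  expect_equal(nrow(bland_altman(est, ref)), 40)
})

test_that("Levene's statistic matches brute force and the car oracle", {
  set.seed(17)
  for (i in 1:20) {
    g <- factor(rep(1:3, each = 30))
    x <- rnorm(90, 0, rep(c(1, 1.5, 2), each = 30))
    ours <- levene_test(x, g)
    # brute force: one-way ANOVA on absolute deviations from group means
    dev <- abs(x - ave(x, g))
    brute <- summary(aov(dev ~ g))[[1]]
    expect_equal(ours$statistic, brute[["F value"]][1],
                 tolerance = 1e-10)
    expect_equal(ours$p_value, brute[["Pr(>F)"]][1], tolerance = 1e-10)
    # independent implementation
    ref <- car::leveneTest(x, g, center = mean)
    expect_equal(ours$statistic, ref[1, "F value"], tolerance = 1e-10)

    bf <- levene_test(x, g, center = "median")
    ref_bf <- car::leveneTest(x, g, center = median)
    expect_equal(bf$statistic, ref_bf[1, "F value"], tolerance = 1e-10)
  }
})

test_that("compare_methods runs the two-factor analysis end to end", {
  set.seed(23)
  subj <- sprintf("S%03d", 1:40)
  grid <- expand.grid(
    algorithm = c("lasso", "boosted_trees", "residual_net"),
    method = c("calibration_free", "personalized"),
    subject_id = subj, stringsAsFactors = FALSE
  )
  grid$error <- rnorm(nrow(grid), 0, ifelse(
    grid$method == "calibration_free", 12, 4
  ))
  out <- compare_methods(grid)
  expect_lt(out$levene_method$p_value, 0.05)
  expect_gt(out$levene_algorithm$p_value, 0.05)
  expect_equal(nrow(out$levene_pairwise), choose(6, 2))
  expect_true(all(out$levene_pairwise$p_adjusted >=
                    out$levene_pairwise$p_value))

  # identical residuals for all algorithms: algorithm factor inert
  same <- grid[order(grid$method, grid$subject_id), ]
  same$error <- rep(rnorm(40 * 2), each = 3)
  out2 <- compare_methods(same)
  tab <- out2$anova[[1]]
  p_alg <- tab[grepl("^algorithm\\s*$", rownames(tab)), "Pr(>F)"]
  expect_gt(p_alg, 0.95)
  expect_gt(out2$levene_algorithm$p_value, 0.95)

  expect_error(compare_methods(grid[grid$algorithm != "lasso" |
                                      grid$method != "personalized", ]),
               "empty cells")
})

test_that("the carry-forward baseline summarizes calibration references", {
  plans <- list(
    plan_pairs(rep(1, 7), subject_id = "A"),
    plan_pairs(c(1, 1.2, 1, 1, 1, 1, 1), subject_id = "B")
  )
  rt <- expand.grid(subject_id = c("A", "B"), segment_index = 1:7,
                    stringsAsFactors = FALSE)
  rt$sbp <- 120 + (rt$subject_id == "B") * 10 + rt$segment_index
  rt$dbp <- rt$sbp - 40
  bs <- ground_truth_baseline(plans, rt, "sbp")
  expect_equal(bs$n, 6) # one per assignment
  # subject A: cal 1 vs tests 2,3,4 -> errors -1,-2,-3
  expect_equal(sort(unname(bs$residuals[1:3])), c(-3, -2, -1))
})
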
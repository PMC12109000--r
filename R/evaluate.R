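#' Summarize blood-pressure estimation errors
#'
#' Computes the mean error (bias), the sample standard deviation of the
#' errors (n - 1 denominator), the mean absolute error, and the fractions of
#' absolute errors within 5, 10 and 15 mm Hg, retaining the per-estimate
#' residuals (estimate minus reference).
#'
#' @param estimates,references Equal-length numeric vectors, mm Hg.
#' @return An object of class `error_summary`: `list(n, me, sd, mae,
#'   residuals, pct_within)`, with `pct_within` as fractions in `[0, 1]`.
#' @export
error_summary <- function(estimates, references) {
  if (length(estimates) != length(references)) {
    stop("estimates and references must have equal length")
  }
  n <- length(estimates)
  if (n == 0) stop("no estimates supplied")
  res <- estimates - references
  if (n < 2) stop("need n >= 2 for the error standard deviation")
  structure(
    list(
      n = n, me = mean(res), sd = sd(res), mae = mean(abs(res)),
      residuals = res,
      pct_within = c(
        le5 = mean(abs(res) <= 5), le10 = mean(abs(res) <= 10),
        le15 = mean(abs(res) <= 15)
      )
    ),
    class = "error_summary"
  )
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf(
    "<error_summary> n=%d  ME %.2f  SD %.2f  MAE %.2f mm Hg\n",
    x$n, x$me, x$sd, x$mae
  ))
  cat(sprintf(
    "  |error| <= 5/10/15 mm Hg: %.1f%% / %.1f%% / %.1f%%\n",
    100 * x$pct_within[1], 100 * x$pct_within[2], 100 * x$pct_within[3]
  ))
  invisible(x)
}

#' Device-accuracy verdict against the AAMI limits
#'
#' Bias (mean error) must not exceed 5 mm Hg in magnitude and the error SD
#' must not exceed 8 mm Hg. Both bounds are applied inclusively.
#'
#' @param summary An [error_summary()].
#' @return `list(bias_pass, sd_pass)`.
#' @export
aami_device_check <- function(summary) {
  list(
    bias_pass = abs(summary$me) <= 5,
    sd_pass = summary$sd <= 8
  )
}

#' Letter grade under the BHS protocol
#'
#' Grade A requires at least 60/85/95 percent of absolute errors within
#' 5/10/15 mm Hg, grade B at least 50/75/90, grade C at least 40/65/80;
#' anything worse is D. All three bounds must hold simultaneously
#' (inclusively) for a grade.
#'
#' @param pct_within Three fractions in `[0, 1]`, non-decreasing: the
#'   fractions of absolute errors within 5, 10 and 15 mm Hg.
#' @return `"A"`, `"B"`, `"C"` or `"D"`.
#' @export
bhs_grade <- function(pct_within) {
  p <- as.numeric(pct_within)
  if (length(p) != 3 || any(p < 0 | p > 1)) {
    stop("pct_within must be three fractions in [0, 1]")
  }
  if (is.unsorted(p)) {
    stop("pct_within must be non-decreasing across the 5/10/15 bounds")
  }
  if (all(p >= c(0.60, 0.85, 0.95))) {
    return("A")
  }
  if (all(p >= c(0.50, 0.75, 0.90))) {
    return("B")
  }
  if (all(p >= c(0.40, 0.65, 0.80))) {
    return("C")
  }
  "D"
}

#' Cohort-composition check against the AAMI test-set criteria
#'
#' The test cohort must contain at least 85 subjects; at least 5% of
#' subjects in each of the categories SBP < 100, SBP > 160, DBP < 60 and
#' DBP > 100 mm Hg; and at least 20% with SBP > 140 and (separately) at
#' least 20% with DBP > 85 mm Hg.
#'
#' @param sbp,dbp Per-subject reference pressures (subject-level means of
#'   segment references), mm Hg.
#' @return `list(pass, n, detail)` where `detail` is a data.frame of each
#'   criterion's fraction, requirement and verdict.
#' @export
aami_cohort_check <- function(sbp, dbp) {
  stopifnot(length(sbp) == length(dbp))
  n <- length(sbp)
  detail <- data.frame(
    criterion = c(
      "n_subjects", "sbp_lt_100", "sbp_gt_160", "dbp_lt_60",
      "dbp_gt_100", "sbp_gt_140", "dbp_gt_85"
    ),
    value = c(
      n, mean(sbp < 100), mean(sbp > 160), mean(dbp < 60),
      mean(dbp > 100), mean(sbp > 140), mean(dbp > 85)
    ),
    required = c(85, 0.05, 0.05, 0.05, 0.05, 0.20, 0.20)
  )
  detail$pass <- detail$value >= detail$required
  list(pass = all(detail$pass), n = n, detail = detail)
}

#' Bland-Altman agreement data
#'
#' Per-pair means and differences (estimate minus reference) with limits of
#' agreement at the mean difference plus or minus twice the SD of the
#' differences.
#'
#' @param estimates,references Paired numeric vectors, mm Hg.
#' @return data.frame with columns `mean` and `difference`; the limits are
#'   attached as attributes `bias`, `lower`, `upper`.
#' @export
bland_altman <- function(estimates, references) {
  if (length(estimates) != length(references)) {
    stop("paired vectors required")
  }
  d <- estimates - references
  m <- (estimates + references) / 2
  s <- if (length(d) > 1) sd(d) else 0
  out <- data.frame(mean = m, difference = d)
  attr(out, "bias") <- mean(d)
  attr(out, "lower") <- mean(d) - 2 * s
  attr(out, "upper") <- mean(d) + 2 * s
  out
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on the absolute deviations of each observation from its
#' group center: the group mean for the classical (absolute) Levene test,
#' or the group median for the Brown-Forsythe variant.
#'
#' @param values Numeric vector of observations (e.g. estimation errors).
#' @param groups Group labels, same length.
#' @param center `"mean"` (default) or `"median"`.
#' @return `list(statistic, df, p_value)`.
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  centers <- tapply(values, groups, if (center == "mean") mean else median)
  dev <- abs(values - centers[groups])
  fit <- aov(dev ~ groups)
  tab <- summary(fit)[[1]]
  list(
    statistic = tab[["F value"]][1],
    df = c(tab[["Df"]][1], tab[["Df"]][2]),
    p_value = tab[["Pr(>F)"]][1]
  )
}

#' Compare algorithms and calibration methods statistically
#'
#' Takes a table of per-estimate signed errors keyed by algorithm and
#' calibration method and runs the study's statistical comparisons:
#' a two-way ANOVA on subject-level mean errors (factors: algorithm and
#' method, with interaction) with Tukey post hoc comparisons, Levene's
#' (absolute) test on each factor, and Bonferroni-corrected pairwise Levene
#' comparisons between all algorithm-method cells.
#'
#' @param residual_table data.frame with columns `algorithm`, `method`,
#'   `subject_id`, `error`.
#' @param alpha Significance threshold (default 0.05).
#' @return list with elements `anova` (the aov fit summary), `posthoc`
#'   (TukeyHSD), `levene_algorithm`, `levene_method`, `levene_pairwise`
#'   (data.frame of cell pairs with Bonferroni-adjusted p-values), `alpha`.
#' @export
compare_methods <- function(residual_table, alpha = 0.05) {
  need <- c("algorithm", "method", "subject_id", "error")
  if (!all(need %in% names(residual_table))) {
    stop("residual_table must have columns ",
         paste(need, collapse = ", "))
  }
  cells <- table(residual_table$algorithm, residual_table$method)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)
    stop(
      "unbalanced design; empty cells: ",
      paste(rownames(cells)[bad[, 1]], colnames(cells)[bad[, 2]],
            sep = "/", collapse = ", ")
    )
  }
  # subject-level mean error per cell is the analysis unit
  agg <- aggregate(
    error ~ algorithm + method + subject_id, residual_table, mean
  )
  agg$algorithm <- factor(agg$algorithm)
  agg$method <- factor(agg$method)
  fit <- aov(error ~ algorithm * method, data = agg)
  lev_alg <- levene_test(agg$error, agg$algorithm)
  lev_met <- levene_test(agg$error, agg$method)
  cell <- interaction(agg$algorithm, agg$method, drop = TRUE)
  pairs <- combn(levels(cell), 2)
  lev_pair <- data.frame(
    cell_a = pairs[1, ], cell_b = pairs[2, ],
    p_value = apply(pairs, 2, function(pr) {
      sel <- cell %in% pr
      levene_test(agg$error[sel], droplevels(cell[sel]))$p_value
    })
  )
  lev_pair$p_adjusted <- p.adjust(lev_pair$p_value, method = "bonferroni")
  list(
    anova = summary(fit),
    posthoc = TukeyHSD(fit),
    levene_algorithm = lev_alg,
    levene_method = lev_met,
    levene_pairwise = lev_pair,
    alpha = alpha
  )
}

#' Carry-forward ground-truth baseline
#'
#' The naive competitor to the model: estimate each tested segment's BP by
#' the reference BP of its assigned calibration segment (the most recent
#' direct measurement), summarized identically to the model errors.
#'
#' @param plans List of [plan_pairs()] results.
#' @param reference_table data.frame with columns `subject_id`,
#'   `segment_index`, and the reference pressure column named by `target`.
#' @param target `"sbp"` or `"dbp"`.
#' @return An [error_summary()].
#' @export
ground_truth_baseline <- function(plans, reference_table,
                                  target = c("sbp", "dbp")) {
  target <- match.arg(target)
  est <- ref <- numeric(0)
  for (p in plans) {
    if (is.null(p)) next
    rt <- reference_table[reference_table$subject_id == p$subject_id, ]
    bp <- setNames(rt[[target]], rt$segment_index)
    est <- c(est, bp[as.character(p$assignments$cal)])
    ref <- c(ref, bp[as.character(p$assignments$test)])
  }
  error_summary(est, ref)
}
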
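segment_mean_ppg <- function(segments) {
  if (is.numeric(segments)) {
    return(segments)
  }
  vapply(segments, function(s) mean(s$ppg), numeric(1))
}

#' Plan the personalization/test pairing of a subject's test segments
#'
#' Implements the test-time personalization protocol on a subject's seven
#' temporally ordered, QC-passing test segments. Segment 1 is the default
#' personalization (calibration) segment and is never tested. The candidate
#' test segments 2, 3 and 4 are paired with reserves 5, 6 and 7. For each
#' pair (a, b): if the mean PPG of segment a differs from the mean PPG of
#' segment 1 by at most `threshold` (relative), segment a is tested with
#' calibration from segment 1 and b goes unused; otherwise the hemodynamic
#' state is assumed to have drifted, segment b is tested with calibration
#' from segment a (a re-calibration), and a goes unused as a test. Exactly
#' three test assignments result per subject.
#'
#' @param segments List of 7 [waveform_segment()]s in ascending `t0` order,
#'   or a numeric vector of their 7 mean PPG values.
#' @param threshold Relative mean-PPG deviation triggering re-calibration
#'   (default 0.05).
#' @param subject_id Optional id recorded in the plan (taken from the
#'   segments when available).
#' @return An object of class `pairing_plan`: `list(subject_id,
#'   assignments (data.frame test, cal, recalibrated), unused)`, or `NULL`
#'   (with a warning) when fewer than 7 segments are supplied.
#' @export
plan_pairs <- function(segments, threshold = 0.05, subject_id = NULL) {
  m <- segment_mean_ppg(segments)
  if (length(m) < 7) {
    warning(
      "subject excluded from personalization: ", length(m),
      " test segments available, 7 required"
    )
    return(NULL)
  }
  m <- m[1:7]
  if (!is.numeric(segments)) {
    t0s <- vapply(segments[1:7], `[[`, numeric(1), "t0")
    if (is.unsorted(t0s, strictly = TRUE)) {
      stop("test segments must be in strictly ascending temporal order")
    }
    subject_id <- subject_id %||% segments[[1]]$subject_id
  }
  if (abs(m[1]) < 1e-8) {
    stop("mean PPG of the default personalization segment is ~0; the ",
         "relative deviation rule is undefined")
  }
  pairs <- list(c(2, 5), c(3, 6), c(4, 7))
  rows <- lapply(pairs, function(ab) {
    a <- ab[1]
    b <- ab[2]
    dev <- abs(m[a] - m[1]) / abs(m[1])
    if (dev <= threshold) {
      data.frame(test = a, cal = 1, recalibrated = FALSE, unused = b)
    } else {
      data.frame(test = b, cal = a, recalibrated = TRUE, unused = a)
    }
  })
  tab <- do.call(rbind, rows)
  structure(
    list(
      subject_id = subject_id %||% NA_character_,
      assignments = tab[, c("test", "cal", "recalibrated")],
      unused = tab$unused,
      threshold = threshold
    ),
    class = "pairing_plan"
  )
}

#' @export
print.pairing_plan <- function(x, ...) {
  cat(sprintf(
    "<pairing_plan> subject %s: tests {%s}, %d re-calibration(s)\n",
    x$subject_id,
    paste(sprintf("%d<-%d", x$assignments$test, x$assignments$cal),
          collapse = ", "),
    sum(x$assignments$recalibrated)
  ))
  invisible(x)
}

#' Fraction of subjects requiring at least one re-calibration
#'
#' @param plans List of [plan_pairs()] results (`NULL` entries, from
#'   excluded subjects, are dropped).
#' @return Fraction in `[0, 1]`.
#' @export
recalibration_rate <- function(plans) {
  plans <- plans[!vapply(plans, is.null, logical(1))]
  if (!length(plans)) stop("no pairing plans supplied")
  mean(vapply(plans, function(p) any(p$assignments$recalibrated),
              logical(1)))
}

#' Sweep the re-calibration threshold and measure the SBP error SD
#'
#' Re-runs the personalized evaluation of a fitted experiment at each
#' candidate mean-PPG threshold and reports the standard deviation of the
#' SBP estimation errors. On drift-bearing cohorts the SD is expected to be
#' non-decreasing in the threshold: a looser threshold leaves more drifted
#' segments tested against a stale calibration.
#'
#' @param experiment A fitted experiment from [run_bp_experiment()] (must
#'   contain a personalized model and the prepared test data).
#' @param thresholds Numeric vector of relative mean-PPG thresholds.
#' @return data.frame with columns `threshold`, `sd`, `me`,
#'   `recalibration_rate`.
#' @export
threshold_sweep <- function(experiment, thresholds = c(0.04, 0.05, 0.06)) {
  rows <- lapply(thresholds, function(th) {
    ev <- evaluate_personalized(
      experiment$models$personalized, experiment$test_features,
      threshold = th
    )
    es <- error_summary(ev$estimate, ev$reference)
    data.frame(
      threshold = th, sd = es$sd, me = es$me,
      recalibration_rate = recalibration_rate(ev$plans)
    )
  })
  do.call(rbind, rows)
}

# Evaluate a personalized model under the pairing protocol.
#
# test_features: per-subject list with elements
#   frame    : data.frame of the 7 test segments' calibration-free features
#              (+ targets, t0) in temporal order
#   cal      : list of 7 cal_summary() entries (ABP mean/sd/t0)
#   mean_ppg : numeric(7)
evaluate_personalized <- function(model, test_features, threshold = 0.05) {
  plans <- list()
  est <- ref <- numeric(0)
  subj <- character(0)
  first_flag <- logical(0)
  target_col <- paste0("target_", model$spec$target)
  for (sid in names(test_features)) {
    tf <- test_features[[sid]]
    plan <- plan_pairs(tf$mean_ppg, threshold = threshold,
                       subject_id = sid)
    plans[[sid]] <- plan
    if (is.null(plan)) next
    a <- plan$assignments
    rows <- tf$frame[a$test, , drop = FALSE]
    rows$cal_abp_mean <- vapply(tf$cal[a$cal], `[[`, numeric(1), "mean")
    rows$cal_abp_sd <- vapply(tf$cal[a$cal], `[[`, numeric(1), "sd")
    # the protocol guard: calibration must precede the tested segment
    stopifnot(all(
      vapply(tf$cal[a$cal], `[[`, numeric(1), "t0") < rows$t0
    ))
    est <- c(est, predict(model, rows))
    ref <- c(ref, rows[[target_col]])
    subj <- c(subj, rep(sid, nrow(rows)))
    first_flag <- c(first_flag, seq_len(nrow(rows)) == 1)
  }
  list(
    estimate = est, reference = ref, subject = subj,
    first_test = first_flag, plans = plans,
    tested = lapply(plans, function(p) {
      if (is.null(p)) NULL else p$assignments$test
    })
  )
}

# Calibration-free evaluation on exactly the same tested segments.
evaluate_calibration_free <- function(model, test_features, tested) {
  est <- ref <- numeric(0)
  subj <- character(0)
  first_flag <- logical(0)
  target_col <- paste0("target_", model$spec$target)
  for (sid in names(test_features)) {
    idx <- tested[[sid]]
    if (is.null(idx)) next
    rows <- test_features[[sid]]$frame[idx, , drop = FALSE]
    est <- c(est, predict(model, rows))
    ref <- c(ref, rows[[target_col]])
    subj <- c(subj, rep(sid, nrow(rows)))
    first_flag <- c(first_flag, seq_len(nrow(rows)) == 1)
  }
  list(estimate = est, reference = ref, subject = subj,
       first_test = first_flag)
}
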
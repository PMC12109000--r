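# Shared fixtures, built once per test run.

fix_spec <- cohort_spec(12, seed = 404)
fix_profile <- make_subject(fix_spec, 1)
fix_segment <- render_segment(fix_profile, 2)
fix_ann <- annotate_segment(fix_segment)

# a small fully featurized dataset (4 subjects x 3 segments)
fix_dataset <- make_dataset(cohort_spec(4, seed = 808), 3)

# deterministic triangular-pulse PPG segment for geometry checks:
# valley -> peak 0.3 s, peak -> next valley 0.5 s, amplitude `amp`
triangle_segment <- function(n_beats = 8, fs = 125, amp = 1) {
  up <- round(0.3 * fs)
  down <- round(0.5 * fs)
  pulse <- c(seq(0, amp, length.out = up + 1)[-1],
             seq(amp, 0, length.out = down + 1)[-1])
  ppg <- c(rep(0, 10), rep(pulse, n_beats), rep(0, 10))
  n <- length(ppg)
  ecg <- rep(0, n)
  abp <- 80 + 40 * ppg / max(ppg)
  seg <- waveform_segment("TRI", 0, fs, ecg, ppg, abp, age = 50, sex = 0)
  valleys <- 10L + (0:n_beats) * (up + down)
  peaks <- head(valleys, -1) + up
  ann <- structure(
    list(
      r_peaks = integer(0), ppg_peaks = as.integer(peaks),
      ppg_valleys = as.integer(valleys), abp_peaks = integer(0),
      abp_valleys = integer(0), abp_systolic = numeric(0),
      abp_diastolic = numeric(0)
    ),
    class = "beat_annotations"
  )
  list(segment = seg, ann = ann, up_s = up / fs, down_s = down / fs,
       amp = amp)
}

# random series generator used by the feature-oracle checks
random_series <- function(n, kind = c("gauss", "ar", "sine", "walk")) {
  kind <- match.arg(kind)
  switch(kind,
    gauss = rnorm(n),
    ar = as.numeric(arima.sim(list(ar = runif(1, 0.3, 0.95)), n)),
    sine = sin(2 * pi * runif(1, 1, 20) * seq_len(n) / n) +
      rnorm(n, 0, runif(1, 0.05, 0.5)),
    walk = cumsum(rnorm(n))
  )
}

python_catch22 <- function(series_list) {
  script <- system.file("python", "catch22_oracle.py",
                        package = "cufflessbp")
  inp <- tempfile(fileext = ".json")
  out <- tempfile(fileext = ".json")
  jsonlite::write_json(series_list, inp, digits = NA, auto_unbox = FALSE)
  status <- system2("python", c(script, inp), stdout = out)
  stopifnot(status == 0)
  res <- jsonlite::fromJSON(out)
  res[vapply(res, is.null, logical(1))] <- NA
  matrix(as.numeric(as.matrix(res)), nrow = length(series_list))
}
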
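#' Names of the 22 canonical time-series features
#'
#' The fixed, ordered names of the canonical 22-feature set computed by
#' [catch22_features()]. The order is part of the model-input contract and
#' never changes.
#'
#' @return Character vector of length 22.
#' @export
catch22_feature_names <- function() {
  c(
    "DN_HistogramMode_5",
    "DN_HistogramMode_10",
    "CO_f1ecac",
    "CO_FirstMin_ac",
    "CO_HistogramAMI_even_2_5",
    "CO_trev_1_num",
    "MD_hrv_classic_pnn40",
    "SB_BinaryStats_mean_longstretch1",
    "SB_BinaryStats_diff_longstretch0",
    "SB_TransitionMatrix_3ac_sumdiagcov",
    "PD_PeriodicityWang_th0_01",
    "CO_Embed2_Dist_tau_d_expfit_meandiff",
    "IN_AutoMutualInfoStats_40_gaussian_fmmi",
    "FC_LocalSimple_mean1_tauresrat",
    "FC_LocalSimple_mean3_stderr",
    "DN_OutlierInclude_p_001_mdrmd",
    "DN_OutlierInclude_n_001_mdrmd",
    "SP_Summaries_welch_rect_area_5_1",
    "SP_Summaries_welch_rect_centroid",
    "SB_MotifThree_quantile_hh",
    "SC_FluctAnal_2_dfa_50_1_2_logi_prop_r1",
    "SC_FluctAnal_2_rsrangefit_50_1_logi_prop_r1"
  )
}

#' Canonical 22-feature characterization of a time series
#'
#' Computes the canonical 22-feature set (distribution shape, linear and
#' nonlinear autocorrelation structure, successive-difference statistics,
#' symbolic motifs, outlier-inclusion timing, rectangular-window spectral
#' summaries, simple local forecasting performance, and fluctuation-analysis
#' scaling-regime proportions) on a single numeric series. The series is
#' z-scored internally (population standard deviation), so the features are
#' invariant to affine rescaling of the input.
#'
#' A constant series has no well-defined z-score; all 22 features are then
#' returned as `NA` with a warning rather than silently propagating NaN.
#'
#' @param x Numeric vector, length at least 100, all values finite.
#' @return Named numeric vector of length 22 (names from
#'   [catch22_feature_names()]).
#' @export
catch22_features <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (length(x) < 100) {
    stop("series too short for the 22-feature set (need >= 100 samples, got ",
         length(x), ")")
  }
  if (!all(is.finite(x))) stop("`x` contains non-finite values")
  out <- .catch22_cpp(as.numeric(x))
  names(out) <- catch22_feature_names()
  if (all(is.na(out))) {
    warning("constant series: all 22 features are undefined (returned NA)")
  }
  out
}
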
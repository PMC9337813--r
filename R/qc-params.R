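#' Feature-quality and preprocessing parameters
#'
#' Thresholds follow the standard pooled-QC acceptance criteria for
#' untargeted metabolomics: pooled-QC RSD < 30%, dilution-series Pearson
#' correlation with the dilution factor > 0.7, and study-sample RSD > 1.1 x
#' pooled-QC RSD. All three inequalities are strict; ties fail.
#'
#' @param rsd_qc_max maximum pooled-QC relative standard deviation, percent.
#' @param dilution_r_min minimum Pearson correlation between dilution-series
#'   intensity and dilution fraction.
#' @param study_to_qc_rsd_ratio_min minimum ratio of study-sample RSD to
#'   pooled-QC RSD (a feature whose variation is mostly technical carries no
#'   biological information).
#' @param loess_span LOESS span used for the drift model, fraction of pooled
#'   QC points per local fit.
#' @param loess_enabled `TRUE`/`FALSE`, or `NULL` to decide from the
#'   platform label: reverse-phase LC-MS lipid platforms are corrected,
#'   HILIC and NMR platforms pass through unchanged.
#' @param glog_lambda generalized-log parameter; `"auto"` estimates it as
#'   the squared median pooled-QC standard deviation of low-intensity
#'   features.
#' @param loess_min_window minimum number of pooled-QC points per local
#'   fit; in batches with few QC injections the span is widened to
#'   `loess_min_window / n_qc` so the drift curve smooths the QC series
#'   instead of interpolating through it (interpolation would absorb the
#'   technical noise and defeat the RSD criterion).
#' @param min_qc_per_batch minimum pooled-QC injections required per batch
#'   for the drift model.
#' @param max_missing_study maximum fraction of missing study values a
#'   feature may have and still pass QC.
#' @return A `qc_params` list.
#' @export
qc_params <- function(rsd_qc_max = 30,
                      dilution_r_min = 0.7,
                      study_to_qc_rsd_ratio_min = 1.1,
                      loess_span = 0.5,
                      loess_enabled = NULL,
                      loess_min_window = 6,
                      glog_lambda = "auto",
                      min_qc_per_batch = 3,
                      max_missing_study = 0.5) {
  assert_that(rsd_qc_max > 0, "rsd_qc_max must be positive")
  assert_that(study_to_qc_rsd_ratio_min > 0, "ratio threshold must be positive")
  assert_that(loess_span > 0 && loess_span <= 1, "loess_span must be in (0, 1]")
  if (!identical(glog_lambda, "auto")) {
    assert_that(is.numeric(glog_lambda) && glog_lambda >= 0,
                "glog_lambda must be non-negative or \"auto\"")
  }
  structure(list(rsd_qc_max = rsd_qc_max, dilution_r_min = dilution_r_min,
                 study_to_qc_rsd_ratio_min = study_to_qc_rsd_ratio_min,
                 loess_span = loess_span, loess_enabled = loess_enabled,
                 loess_min_window = loess_min_window,
                 glog_lambda = glog_lambda,
                 min_qc_per_batch = min_qc_per_batch,
                 max_missing_study = max_missing_study),
            class = "qc_params")
}

# platform default for run-order correction: needed on reverse-phase LC-MS
# lipid assays, not on HILIC+ or NMR
platform_loess_default <- function(platform) {
  !grepl("HILIC|NMR", platform, ignore.case = TRUE)
}
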
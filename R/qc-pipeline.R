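#' Run the full QC preprocessing stage
#'
#' Drift-corrects a raw intensity matrix against the pooled QC samples,
#' computes per-feature quality metrics, applies the three feature-selection
#' criteria, and returns the retained features glog-transformed and
#' autoscaled, ready for association testing.
#'
#' @param x an [intensity_matrix()] in state `raw`.
#' @param manifest sample manifest.
#' @param params a [qc_params()].
#' @return list with `corrected` (full corrected matrix), `feature_qc`
#'   (metrics + pass/fail flags), `scaled` (passing features, transformed
#'   and autoscaled), `scaling` (per-feature centre/scale), `glog_lambda`,
#'   `drift_diagnostics` and `report` (criterion failure counts and the
#'   parameters used).
#' @export
qc_pipeline <- function(x, manifest, params = qc_params()) {
  dc <- loess_drift_correct(x, manifest, params)
  fqc <- feature_quality(dc$corrected, manifest, params)
  fqc <- filter_features(fqc, params)
  report <- attr(fqc, "report")

  keep <- fqc$feature_id[fqc$pass_overall]
  vals <- as.matrix(dc$corrected)[keep, , drop = FALSE]
  sub <- intensity_matrix(vals, state = "corrected", platform = x$platform)
  trans <- glog_transform(sub, lambda = params$glog_lambda,
                          manifest = manifest)
  sc <- autoscale(trans, manifest)
  report$n_scaled <- nrow(as.matrix(sc$scaled))
  report$n_zero_variance_dropped <- nrow(sc$dropped)
  report$glog_lambda <- attr(trans, "glog_lambda")
  list(corrected = dc$corrected, feature_qc = fqc, scaled = sc$scaled,
       scaling = sc$stats, glog_lambda = attr(trans, "glog_lambda"),
       drift_diagnostics = dc$diagnostics, report = report)
}

#' Map scaled study intensities to subjects
#'
#' Extracts the study-sample columns of a (scaled) intensity matrix and
#' renames them to subject ids; subjects with several study samples get the
#' per-feature mean.
#'
#' @param x an [intensity_matrix()].
#' @param manifest sample manifest.
#' @return matrix, features x subjects.
#' @export
metabolites_by_subject <- function(x, manifest) {
  v <- as.matrix(x)
  idx <- match(colnames(v), manifest$sample_id)
  assert_that(!anyNA(idx), "manifest does not cover all samples")
  study <- manifest$sample_type[idx] == "study"
  v <- v[, study, drop = FALSE]
  subj <- manifest$subject_id[idx][study]
  if (anyDuplicated(subj)) {
    agg <- vapply(split(seq_along(subj), subj),
                  function(j) rowMeans(v[, j, drop = FALSE], na.rm = TRUE),
                  numeric(nrow(v)))
    return(agg)
  }
  colnames(v) <- subj
  v
}
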
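#' Relative standard deviation
#'
#' RSD = 100 x sample standard deviation / mean, the precision metric used
#' for pooled-QC and study-sample variability. Undefined (returns `NA`) when
#' fewer than two non-missing values are available or the mean is not
#' positive; a feature with an undefined RSD fails the corresponding QC
#' criterion.
#'
#' @param values numeric vector of intensities (missing allowed).
#' @return RSD in percent, or `NA_real_` when undefined.
#' @export
compute_rsd <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (m <= 0) return(NA_real_)
  100 * stats::sd(x) / m
}

#' Dilution-series response
#'
#' Pearson correlation between each feature's intensity in the dilution-QC
#' samples and the dilution fraction. A feature whose signal responds
#' linearly to analyte amount correlates strongly with the fraction; a flat
#' (zero-variance) or erratic response yields an undefined or low
#' correlation and fails QC.
#'
#' @param x an [intensity_matrix()].
#' @param manifest sample manifest with `sample_type` and
#'   `dilution_fraction`.
#' @return tibble with `feature_id`, `dilution_r` (`NA` when undefined) and
#'   `n_dilution_used`.
#' @export
dilution_response <- function(x, manifest) {
  v <- as.matrix(x)
  idx <- match(colnames(v), manifest$sample_id)
  assert_that(!anyNA(idx), "manifest does not cover all samples")
  dil <- manifest$sample_type[idx] == "dilution_qc"
  fids <- rownames(v)
  if (!any(dil)) {
    return(tibble::tibble(feature_id = fids, dilution_r = NA_real_,
                          n_dilution_used = 0L))
  }
  fr <- manifest$dilution_fraction[idx][dil]
  vd <- v[, dil, drop = FALSE]
  res <- vapply(seq_len(nrow(vd)), function(i) {
    y <- vd[i, ]
    ok <- !is.na(y)
    if (length(unique(fr[ok])) < 3L) return(c(NA_real_, sum(ok)))
    if (sd_na(y[ok]) %in% c(0, NA)) return(c(NA_real_, sum(ok)))
    c(stats::cor(y[ok], fr[ok]), sum(ok))
  }, numeric(2))
  tibble::tibble(feature_id = fids, dilution_r = res[1, ],
                 n_dilution_used = as.integer(res[2, ]))
}

#' Per-feature quality metrics
#'
#' Computes, on a drift-corrected matrix, the pooled-QC RSD, study-sample
#' RSD, dilution-series correlation and missingness per feature.
#'
#' @param x an [intensity_matrix()] in state `corrected` (or `raw`, for
#'   diagnostics on uncorrected data).
#' @param manifest sample manifest.
#' @param params a [qc_params()].
#' @return tibble, one row per feature: `feature_id`, `rsd_qc`, `rsd_study`,
#'   `dilution_r`, `n_qc_used`, `n_dilution_used`, `missing_study`.
#' @export
feature_quality <- function(x, manifest, params = qc_params()) {
  v <- as.matrix(x)
  idx <- match(colnames(v), manifest$sample_id)
  assert_that(!anyNA(idx), "manifest does not cover all samples")
  type <- manifest$sample_type[idx]
  qc <- v[, type == "pooled_qc", drop = FALSE]
  st <- v[, type == "study", drop = FALSE]
  dil <- dilution_response(x, manifest)
  tibble::tibble(
    feature_id = rownames(v),
    rsd_qc = unname(apply(qc, 1, compute_rsd)),
    rsd_study = unname(apply(st, 1, compute_rsd)),
    dilution_r = dil$dilution_r,
    n_qc_used = unname(as.integer(rowSums(!is.na(qc)))),
    n_dilution_used = dil$n_dilution_used,
    missing_study = unname(rowMeans(is.na(st))))
}

#' Apply the feature-selection criteria
#'
#' Marks each feature pass/fail on the three analytical-quality criteria
#' (strict inequalities): pooled-QC RSD below `rsd_qc_max`, dilution-series
#' correlation above `dilution_r_min`, and study RSD above
#' `study_to_qc_rsd_ratio_min` x pooled-QC RSD. The dilution criterion is
#' vacuously true for runs without a dilution series (e.g. NMR). Features
#' with more than `max_missing_study` missing study values also fail.
#' Undefined metrics fail their criterion.
#'
#' @param fqc tibble from [feature_quality()].
#' @param params a [qc_params()].
#' @return `fqc` with logical columns `pass_rsd_qc`, `pass_dilution`,
#'   `pass_variance_ratio`, `pass_missing`, `pass_overall` and a `reason`
#'   string; the per-criterion failure counts are attached as
#'   `attr(, "report")`.
#' @export
filter_features <- function(fqc, params = qc_params()) {
  has_dilution <- any(fqc$n_dilution_used > 0)
  pass_rsd <- !is.na(fqc$rsd_qc) & fqc$rsd_qc < params$rsd_qc_max
  pass_dil <- if (has_dilution) {
    !is.na(fqc$dilution_r) & fqc$dilution_r > params$dilution_r_min
  } else rep(TRUE, nrow(fqc))
  pass_ratio <- !is.na(fqc$rsd_qc) & !is.na(fqc$rsd_study) &
    fqc$rsd_study > params$study_to_qc_rsd_ratio_min * fqc$rsd_qc
  pass_miss <- fqc$missing_study <= params$max_missing_study
  overall <- pass_rsd & pass_dil & pass_ratio & pass_miss
  reason <- rep("", nrow(fqc))
  reason[!pass_miss] <- "excess missing study values"
  reason[!pass_ratio] <- "study RSD not above 1.1x QC RSD"
  reason[!pass_dil] <- "dilution series not linear"
  reason[!pass_rsd] <- "pooled-QC RSD too high"
  out <- dplyr::mutate(fqc, pass_rsd_qc = pass_rsd, pass_dilution = pass_dil,
                       pass_variance_ratio = pass_ratio,
                       pass_missing = pass_miss, pass_overall = overall,
                       reason = ifelse(overall, "", reason))
  attr(out, "report") <- list(
    n_features = nrow(fqc),
    n_pass = sum(overall),
    fail_rsd_qc = sum(!pass_rsd),
    fail_dilution = sum(!pass_dil),
    fail_variance_ratio = sum(!pass_ratio),
    fail_missing = sum(!pass_miss),
    dilution_series_present = has_dilution,
    params = unclass(params))
  out
}
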
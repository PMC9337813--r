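#' Pooled-QC LOESS drift correction
#'
#' Removes run-order and batch-related intensity drift. Per feature and per
#' batch, a locally linear LOESS curve is fitted to pooled-QC intensity
#' versus run order; every sample's intensity is divided by the curve value
#' at its run order (run orders beyond the first/last QC injection are held
#' at the nearest fitted QC value, avoiding edge extrapolation) and rescaled
#' to the feature's reference level, the median pooled-QC intensity across
#' the whole run. Dividing by a per-batch curve and rescaling to a global QC
#' reference removes within-batch drift and between-batch offsets at once,
#' and preserves the median pooled-QC intensity of every feature exactly.
#'
#' Features for which the fit is degenerate (non-positive or non-finite
#' fitted values, or a LOESS failure) are returned uncorrected and flagged
#' in the diagnostics. Platforms that do not need correction
#' (`loess_enabled = FALSE`, the default for HILIC and NMR labels) pass
#' through unchanged with the state still advanced to `corrected`.
#'
#' @param x an [intensity_matrix()] in state `raw`.
#' @param manifest sample manifest.
#' @param params a [qc_params()].
#' @return list with `corrected` (an [intensity_matrix()], state
#'   `corrected`) and `diagnostics` (tibble: `feature_id`, `corrected`
#'   logical, `reason`).
#' @export
loess_drift_correct <- function(x, manifest, params = qc_params()) {
  x <- advance_state(x, "raw", "raw")  # type check only
  v <- as.matrix(x)
  idx <- match(colnames(v), manifest$sample_id)
  assert_that(!anyNA(idx), "manifest does not cover all samples")
  man <- manifest[idx, ]
  fids <- rownames(v)

  enabled <- params$loess_enabled %||% platform_loess_default(x$platform)
  if (!isTRUE(enabled)) {
    out <- intensity_matrix(v, state = "corrected", platform = x$platform)
    diag <- tibble::tibble(feature_id = fids, corrected = FALSE,
                           reason = "correction disabled for platform")
    return(list(corrected = out, diagnostics = diag))
  }

  is_qc <- man$sample_type == "pooled_qc"
  batches <- sort(unique(man$batch))
  for (b in batches) {
    n_qc_b <- sum(is_qc & man$batch == b)
    if (n_qc_b < params$min_qc_per_batch) {
      stop(sprintf("batch %s has only %d pooled QC samples (need >= %d)",
                   b, n_qc_b, params$min_qc_per_batch), call. = FALSE)
    }
  }

  corrected <- v
  flag <- rep(TRUE, length(fids))
  reason <- rep("", length(fids))
  ro <- man$run_order
  for (i in seq_along(fids)) {
    fitted_all <- rep(NA_real_, ncol(v))
    ok <- TRUE
    for (b in batches) {
      in_b <- man$batch == b
      qb <- which(in_b & is_qc & !is.na(v[i, ]))
      if (length(qb) < params$min_qc_per_batch) { ok <- FALSE; break }
      span_b <- max(params$loess_span,
                    min(1, params$loess_min_window / length(qb)))
      fit <- tryCatch(
        suppressWarnings(stats::loess(
          y ~ r, data = data.frame(y = v[i, qb], r = ro[qb]),
          span = span_b, degree = 1, family = "gaussian",
          control = stats::loess.control(surface = "direct"))),
        error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      # hold the nearest fitted QC value beyond the QC run-order range
      r_eval <- clamp(ro[in_b], min(ro[qb]), max(ro[qb]))
      pred <- tryCatch(stats::predict(fit, data.frame(r = r_eval)),
                       error = function(e) rep(NA_real_, length(r_eval)))
      if (any(!is.finite(pred)) || any(pred <= 0)) { ok <- FALSE; break }
      fitted_all[in_b] <- pred
    }
    if (!ok) {
      flag[i] <- FALSE
      reason[i] <- "degenerate LOESS fit; returned uncorrected"
      next
    }
    ratio <- v[i, ] / fitted_all
    ref <- stats::median(v[i, is_qc], na.rm = TRUE)
    med_ratio <- stats::median(ratio[is_qc], na.rm = TRUE)
    if (!is.finite(ref) || !is.finite(med_ratio) || med_ratio <= 0) {
      flag[i] <- FALSE
      reason[i] <- "degenerate QC reference; returned uncorrected"
      next
    }
    corrected[i, ] <- ratio * ref / med_ratio
  }
  list(corrected = intensity_matrix(corrected, state = "corrected",
                                    platform = x$platform),
       diagnostics = tibble::tibble(feature_id = fids, corrected = flag,
                                    reason = reason))
}
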
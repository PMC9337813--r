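#' Generalized log transformation
#'
#' `glog(x) = ln((x + sqrt(x^2 + lambda)) / 2)`, a variance-stabilizing
#' transform that behaves like `ln(x)` for large intensities, is defined at
#' zero, and damps the variance inflation of low-intensity features. At
#' `lambda = 0` it reduces exactly to the natural logarithm.
#'
#' @param x an [intensity_matrix()] in state `corrected`, or a bare numeric
#'   vector/matrix (returned as such).
#' @param lambda non-negative transform parameter, or `"auto"` to estimate
#'   it as the squared median pooled-QC standard deviation of low-intensity
#'   features (those with mean intensity below the feature median), a proxy
#'   for the additive-noise variance floor. `"auto"` requires `manifest`.
#' @param manifest sample manifest (needed for `lambda = "auto"`).
#' @return Transformed object of the same type; for an intensity matrix the
#'   state advances to `transformed` and the lambda used is stored in
#'   `attr(, "glog_lambda")`.
#' @export
glog_transform <- function(x, lambda = 0, manifest = NULL) {
  if (is.numeric(x)) {
    assert_that(is.numeric(lambda) && length(lambda) == 1 && lambda >= 0,
                "lambda must be a non-negative number")
    return(glog(x, lambda))
  }
  x <- advance_state(x, "corrected", "corrected")
  if (identical(lambda, "auto")) {
    lambda <- estimate_glog_lambda(x, manifest)
  }
  assert_that(is.numeric(lambda) && length(lambda) == 1 && lambda >= 0,
              "lambda must be a non-negative number")
  out <- intensity_matrix(glog(as.matrix(x), lambda), state = "transformed",
                          platform = x$platform)
  attr(out, "glog_lambda") <- lambda
  out
}

glog <- function(x, lambda) log((x + sqrt(x^2 + lambda)) / 2)

estimate_glog_lambda <- function(x, manifest) {
  assert_that(!is.null(manifest), "lambda = \"auto\" needs the manifest")
  v <- as.matrix(x)
  idx <- match(colnames(v), manifest$sample_id)
  qc <- v[, manifest$sample_type[idx] == "pooled_qc", drop = FALSE]
  if (ncol(qc) < 2) return(0)
  fmean <- rowMeans(qc, na.rm = TRUE)
  low <- fmean <= stats::median(fmean, na.rm = TRUE)
  sds <- apply(qc[low, , drop = FALSE], 1, sd_na)
  lam <- stats::median(sds, na.rm = TRUE)^2
  if (!is.finite(lam)) 0 else lam
}

#' Autoscaling (unit-variance scaling)
#'
#' Mean-centres each feature and divides by its sample standard deviation,
#' computed across non-missing *study* samples only, so one unit equals one
#' standard deviation of the metabolite across participants. The stored
#' centre/scale statistics are applied to all samples (QC columns included)
#' and returned for reuse. Features with zero variance are dropped with
#' reason "zero variance".
#'
#' @param x an [intensity_matrix()] in state `transformed`.
#' @param manifest sample manifest; `NULL` treats all columns as study
#'   samples.
#' @return list with `scaled` (state `scaled`), `stats` (tibble
#'   `feature_id`, `mean`, `sd`) and `dropped` (tibble `feature_id`,
#'   `reason`).
#' @export
autoscale <- function(x, manifest = NULL) {
  x <- advance_state(x, "transformed", "transformed")
  v <- as.matrix(x)
  if (is.null(manifest)) {
    study <- v
  } else {
    idx <- match(colnames(v), manifest$sample_id)
    study <- v[, manifest$sample_type[idx] == "study", drop = FALSE]
  }
  m <- rowMeans(study, na.rm = TRUE)
  s <- apply(study, 1, sd_na)
  bad <- !is.finite(s) | s == 0
  dropped <- tibble::tibble(feature_id = rownames(v)[bad],
                            reason = "zero variance")
  keep <- !bad
  scaled <- (v[keep, , drop = FALSE] - m[keep]) / s[keep]
  list(scaled = intensity_matrix(scaled, state = "scaled",
                                 platform = x$platform),
       stats = tibble::tibble(feature_id = rownames(v)[keep],
                              mean = unname(m[keep]), sd = unname(s[keep])),
       dropped = dropped)
}
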
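#' Baseline outcome table
#'
#' Extracts the baseline (`time == 0`) visit of every raw outcome into a
#' wide table, one row per subject.
#'
#' @param visits long visit table (`subject_id`, `time`, `outcome`,
#'   `value`).
#' @return wide tibble, `subject_id` plus one column per raw outcome.
#' @export
baseline_outcomes <- function(visits) {
  b <- visits[visits$time == 0, c("subject_id", "outcome", "value")]
  tidyr::pivot_wider(b, names_from = "outcome", values_from = "value")
}

#' Orient and standardize the outcome panel
#'
#' Applies the study's outcome conventions: white matter hyperintensity
#' volume is analysed as `log(wmh_percent)`; brain atrophy as the inverse
#' of total brain volume (implemented as a sign flip of the z-scored
#' volume); MDNPH, cognition scores and the Barthel index are sign-flipped
#' so that a higher oriented value always means greater SVD burden or worse
#' cognition. Each continuous end point is then z-scored (mean 0, sample
#' SD 1 across subjects with non-missing values). Binary end points
#' (presence of microbleeds / lacunes) and the simple 0-3 SVD score are
#' derived alongside.
#'
#' @param baseline wide baseline table from [baseline_outcomes()].
#' @param orientation named sign vector, see [default_orientation()].
#' @return list with `z` (tibble of z-scored oriented end points),
#'   `binary` (tibble of logical end points), `fazekas` (grades),
#'   `scaling` (tibble `outcome`, `sign`, `mean`, `sd` of the oriented
#'   values, so raw values are recoverable).
#' @export
orient_and_scale_outcomes <- function(baseline,
                                      orientation = default_orientation()) {
  src <- endpoint_raw_source()
  raw <- list()
  for (ep in names(src)) {
    if (!src[[ep]] %in% names(baseline)) next
    v <- baseline[[src[[ep]]]]
    if (ep == "log_wmh") v <- log(ifelse(v > 0, v, NA_real_))
    raw[[ep]] <- v
  }
  binary <- tibble::tibble(
    subject_id = baseline$subject_id,
    microbleed_presence = baseline$microbleed_count > 0,
    lacune_presence = baseline$lacune_count > 0)
  raw[["simple_svd_score"]] <- simple_svd_score(
    binary$microbleed_presence, baseline$lacune_count,
    baseline$fazekas_grade)

  z <- tibble::tibble(subject_id = baseline$subject_id)
  scaling <- list()
  for (ep in names(raw)) {
    sgn <- orientation[[ep]]
    v <- sgn * raw[[ep]]
    m <- mean(v, na.rm = TRUE)
    s <- sd_na(v)
    if (!is.finite(s) || s == 0) {
      stop("outcome '", ep, "' has zero variance", call. = FALSE)
    }
    z[[ep]] <- (v - m) / s
    scaling[[ep]] <- tibble::tibble(outcome = ep, sign = sgn, mean = m, sd = s)
  }
  list(z = z, binary = binary,
       fazekas = stats::setNames(baseline$fazekas_grade, baseline$subject_id),
       scaling = dplyr::bind_rows(scaling))
}

#' Simple MRI SVD severity score
#'
#' A 0-3 point score summing the presence of cerebral microbleeds, the
#' presence of lacunes, and confluent white matter hyperintensities (Fazekas
#' grade at or above a cut-off). Cut-offs are configurable; a missing
#' component makes the score missing for that subject.
#'
#' @param microbleed_presence logical.
#' @param lacune_count integer lacune count.
#' @param fazekas_grade Fazekas grade 0-3.
#' @param lacune_min minimum lacune count scoring a point (default 1).
#' @param fazekas_min minimum Fazekas grade scoring a point (default 2).
#' @return integer vector in `[0, 3]` (NA where any component is missing).
#' @export
simple_svd_score <- function(microbleed_presence, lacune_count, fazekas_grade,
                             lacune_min = 1, fazekas_min = 2) {
  as.integer(microbleed_presence) + as.integer(lacune_count >= lacune_min) +
    as.integer(fazekas_grade >= fazekas_min)
}

#' Annualized change in an outcome
#'
#' The difference between the latest non-missing follow-up value and the
#' baseline value, divided by the elapsed follow-up time; intermediate
#' visits are ignored. Subjects with only a baseline value (or a missing
#' baseline) get `NA` and are excluded from change models.
#'
#' @param values outcome values by visit.
#' @param times visit times in years (same length; baseline is the earliest
#'   time).
#' @return change per year, or `NA_real_`.
#' @export
annualized_change <- function(values, times) {
  assert_that(length(values) == length(times), "values/times length mismatch")
  if (length(values) < 2L) return(NA_real_)
  o <- order(times)
  values <- values[o]; times <- times[o]
  base_v <- values[1L]; base_t <- times[1L]
  if (is.na(base_v)) return(NA_real_)
  ok <- which(!is.na(values[-1L])) + 1L
  if (!length(ok)) return(NA_real_)
  last <- max(ok)
  if (times[last] <= base_t) return(NA_real_)
  unname((values[last] - base_v) / (times[last] - base_t))
}

#' Annualized changes for every subject and end point
#'
#' Computes [annualized_change()] per subject on the end-point scale
#' (`log_wmh` uses the log of the per-visit WMH percentage; brain atrophy
#' uses total brain volume, oriented downstream).
#'
#' @param visits long visit table.
#' @return wide tibble, `subject_id` plus one change column per continuous
#'   end point (end-point names, un-oriented raw scale).
#' @export
annualized_changes <- function(visits) {
  src <- endpoint_raw_source()
  src <- src[!names(src) %in% "simple_svd_score"]
  v <- visits[visits$outcome %in% src, ]
  v$endpoint <- names(src)[match(v$outcome, src)]
  v$value <- ifelse(v$endpoint == "log_wmh",
                    log(ifelse(v$value > 0, v$value, NA_real_)), v$value)
  ch <- dplyr::summarise(
    dplyr::group_by(v, .data$subject_id, .data$endpoint),
    change = annualized_change(.data$value, .data$time), .groups = "drop")
  tidyr::pivot_wider(ch, names_from = "endpoint", values_from = "change")
}
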
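#' Simulation configuration
#'
#' Defines the analytical-run and clinical-cohort structure the synthetic
#' data generator emulates. Defaults follow the study design the pipeline is
#' built for: two cohorts of symptomatic SVD patients (121 and 503 subjects),
#' pooled QC samples interspersed among study injections, a dilution series
#' (10 x 100%, 5 x 80%, 3 x 60%, 3 x 40%, 5 x 20%, 10 x 1%) run at the start
#' and end of each batch, smooth multiplicative run-order drift plus batch
#' offsets, and lognormal technical/biological variation.
#'
#' @param n_subjects named integer vector, subjects per cohort. Defaults to
#'   `c(cohort_A = 121, cohort_B = 503)`: a smaller severe-SVD stroke cohort
#'   and a larger 50-85 year community SVD cohort.
#' @param n_features number of metabolite features.
#' @param n_batches number of analytical batches.
#' @param qc_interval a pooled QC sample is injected after every
#'   `qc_interval` study samples (and at each batch boundary).
#' @param dilution_design data frame with columns `fraction` (in (0, 1]) and
#'   `replicates`; the full design is injected at the start and end of each
#'   batch.
#' @param drift_amplitude maximum relative multiplicative drift within a
#'   batch (0.1 = up to 10% intensity change across the batch).
#' @param batch_offset_sd log-scale SD of per-(batch, feature) multiplicative
#'   offsets.
#' @param tech_cv technical coefficient of variation (lognormal noise; the
#'   expected pooled-QC RSD for a drift-free feature equals `100 * tech_cv`).
#' @param bio_cv biological coefficient of variation across subjects.
#' @param effect_matrix numeric matrix of true standardized effects,
#'   `n_features` rows, columns named from [effect_endpoints()]. `NULL`
#'   (default) means all-zero (global null).
#' @param covariate_effects named vector: contribution of standardized age,
#'   cohort B membership, and male sex to each oriented outcome latent.
#' @param dementia_base_hazard baseline dementia hazard, events per
#'   person-year.
#' @param dementia_age_loghr log hazard ratio per year of age on the
#'   dementia hazard (0 gives a constant marginal hazard under the global
#'   null).
#' @param censor_years named vector, administrative censoring per cohort
#'   (default 5 years for cohort A, 14 for cohort B).
#' @param visit_years named list of follow-up visit times per cohort
#'   (default `cohort_A` = 0,1,2,3 and `cohort_B` = 0,5,9,14).
#' @param frac_high_rsd,frac_nonlinear,frac_low_biovar fractions of features
#'   planted to violate, respectively, the pooled-QC RSD criterion, the
#'   dilution-linearity criterion, and the study-to-QC variance-ratio
#'   criterion.
#' @param missing_rate missing-completely-at-random rate applied to
#'   intensities and follow-up visits (default 0, off).
#' @param simulate_visits generate follow-up visits (set `FALSE` for
#'   baseline-only simulations).
#' @param platform platform label attached to the run.
#' @param seed integer RNG seed; identical config + seed gives identical
#'   output.
#' @return A `sim_config` object (list).
#' @export
sim_config <- function(n_subjects = c(cohort_A = 121, cohort_B = 503),
                       n_features = 100,
                       n_batches = 2,
                       qc_interval = 10,
                       dilution_design = default_dilution_design(),
                       drift_amplitude = 0.10,
                       batch_offset_sd = 0.10,
                       tech_cv = 0.05,
                       bio_cv = 0.50,
                       effect_matrix = NULL,
                       covariate_effects = c(age = 0.35, cohort_B = -0.3, male = 0.1),
                       dementia_base_hazard = 0.02,
                       dementia_age_loghr = 0.04,
                       censor_years = c(cohort_A = 5, cohort_B = 14),
                       visit_years = list(cohort_A = c(0, 1, 2, 3),
                                          cohort_B = c(0, 5, 9, 14)),
                       frac_high_rsd = 0,
                       frac_nonlinear = 0,
                       frac_low_biovar = 0,
                       missing_rate = 0,
                       simulate_visits = TRUE,
                       platform = "lipid RPC+",
                       seed = 1L) {
  assert_that(length(n_subjects) >= 1 && all(n_subjects >= 1) &&
                all(n_subjects == floor(n_subjects)),
              "n_subjects must be positive integers")
  if (is.null(names(n_subjects))) {
    names(n_subjects) <- paste0("cohort_", LETTERS[seq_along(n_subjects)])
  }
  assert_that(is_count(n_features), "n_features must be a positive integer")
  assert_that(is_count(n_batches), "n_batches must be a positive integer")
  assert_that(is_count(qc_interval), "qc_interval must be a positive integer")
  assert_that(is.data.frame(dilution_design) &&
                all(c("fraction", "replicates") %in% names(dilution_design)),
              "dilution_design needs columns fraction, replicates")
  assert_that(all(dilution_design$fraction > 0 & dilution_design$fraction <= 1),
              "dilution fractions must lie in (0, 1]")
  assert_that(all(dilution_design$replicates >= 1),
              "dilution replicate counts must be >= 1")
  assert_that(drift_amplitude >= 0, "drift_amplitude must be >= 0")
  assert_that(batch_offset_sd >= 0, "batch_offset_sd must be >= 0")
  assert_that(tech_cv >= 0, "negative technical CV")
  assert_that(bio_cv >= 0, "negative biological CV")
  assert_that(dementia_base_hazard >= 0, "dementia_base_hazard must be >= 0")
  assert_that(all(censor_years >= 0), "censor_years must be >= 0")
  assert_that(missing_rate >= 0 && missing_rate < 1,
              "missing_rate must be in [0, 1)")
  if (is.null(effect_matrix)) {
    effect_matrix <- matrix(0, n_features, length(effect_endpoints()),
                            dimnames = list(NULL, effect_endpoints()))
  }
  assert_that(nrow(effect_matrix) == n_features,
              "effect_matrix must have n_features rows")
  assert_that(all(colnames(effect_matrix) %in% effect_endpoints()),
              "unknown effect_matrix column; see effect_endpoints()")
  cfg <- list(n_subjects = n_subjects, n_features = n_features,
              n_batches = n_batches, qc_interval = qc_interval,
              dilution_design = dilution_design,
              drift_amplitude = drift_amplitude,
              batch_offset_sd = batch_offset_sd,
              tech_cv = tech_cv, bio_cv = bio_cv,
              effect_matrix = effect_matrix,
              covariate_effects = covariate_effects,
              dementia_base_hazard = dementia_base_hazard,
              dementia_age_loghr = dementia_age_loghr,
              censor_years = censor_years, visit_years = visit_years,
              frac_high_rsd = frac_high_rsd,
              frac_nonlinear = frac_nonlinear,
              frac_low_biovar = frac_low_biovar,
              missing_rate = missing_rate,
              simulate_visits = isTRUE(simulate_visits),
              platform = platform, seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_dilution_design <- function() {
  data.frame(fraction   = c(1, 0.8, 0.6, 0.4, 0.2, 0.01),
             replicates = c(10, 5, 3, 3, 5, 10))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d subjects (%s), %d features, %d batches, ",
                     "QC every %d, seed %d\n"),
              sum(x$n_subjects),
              paste(sprintf("%s=%d", names(x$n_subjects), x$n_subjects),
                    collapse = ", "),
              x$n_features, x$n_batches, x$qc_interval, x$seed))
  invisible(x)
}

#' Helper to plant effects in a simulation
#'
#' Returns an all-zero effect matrix with the requested entries set, for use
#' as `sim_config(effect_matrix = )`.
#'
#' @param n_features number of features.
#' @param effects data frame with columns `feature` (index), `endpoint`
#'   (from [effect_endpoints()]) and `beta`.
#' @return numeric matrix `n_features` x `length(effect_endpoints())`.
#' @export
plant_effects <- function(n_features, effects) {
  em <- matrix(0, n_features, length(effect_endpoints()),
               dimnames = list(NULL, effect_endpoints()))
  if (nrow(effects)) {
    assert_that(all(effects$endpoint %in% effect_endpoints()),
                "unknown endpoint in `effects`")
    assert_that(all(effects$feature >= 1 & effects$feature <= n_features),
                "feature index out of range")
    em[cbind(effects$feature, match(effects$endpoint, colnames(em)))] <-
      effects$beta
  }
  em
}
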
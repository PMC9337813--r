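#' Simulate a two-cohort clinical SVD population
#'
#' Generates subjects with demographics, vascular risk factors, standardized
#' latent metabolite levels, baseline and follow-up outcomes, and
#' right-censored dementia times. Continuous outcomes are linear in the
#' standardized metabolite levels with the planted effects from
#' `config$effect_matrix` (in SD units of the oriented outcome), plus
#' covariate contributions and Gaussian noise scaled so the oriented outcome
#' has (approximately) unit variance; binary outcomes use a logistic link;
#' dementia times are exponential with log-hazard linear in the planted
#' predictors, censored administratively per cohort.
#'
#' @param config a [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{subjects}{tibble, one row per subject: `subject_id`, `cohort`,
#'       `age`, `sex`, `diabetes`, `hypertension`, `hypercholesterolaemia`,
#'       `dementia_event`, `dementia_time`.}
#'     \item{visits}{tibble in long format: `subject_id`, `time` (years from
#'       baseline), `outcome` (raw measure name), `value`. Baseline is
#'       `time == 0`.}
#'     \item{metabolite_z}{matrix, features x subjects, the true standardized
#'       biological metabolite levels used for effect planting (ground
#'       truth).}
#'   }
#' @export
simulate_subjects <- function(config) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(child_seed(config$seed, 2))
  cohorts <- names(config$n_subjects)
  if (length(cohorts) < 2) {
    warning("single-cohort population: downstream cohort adjustment will drop",
            " the constant cohort term", call. = FALSE)
  }
  subj <- dplyr::bind_rows(lapply(seq_along(cohorts), function(i) {
    n <- config$n_subjects[i]
    co <- cohorts[i]
    # cohort A is the older, more severe stroke cohort
    age_mean <- if (i == 1) 70 else 65.5
    tibble::tibble(
      subject_id = sprintf("%s_%04d", co, seq_len(n)),
      cohort = co,
      age = round(clamp(rnorm(n, age_mean, 9), 45, 90), 1),
      sex = ifelse(runif(n) < 0.58, "male", "female"),
      diabetes = runif(n) < ifelse(i == 1, 0.20, 0.15),
      hypertension = runif(n) < ifelse(i == 1, 0.75, 0.68),
      hypercholesterolaemia = runif(n) < ifelse(i == 1, 0.65, 0.55))
  }))
  n <- nrow(subj)
  nf <- config$n_features

  # true standardized metabolite levels, features x subjects
  M <- matrix(rnorm(nf * n), nf, n,
              dimnames = list(feature_ids(nf), subj$subject_id))

  ce <- config$covariate_effects
  z_age <- as.numeric(scale(subj$age))
  cov_sys <- ce[["age"]] * z_age +
    ce[["cohort_B"]] * as.numeric(subj$cohort == cohorts[min(2, length(cohorts))] &
                                    length(cohorts) > 1) +
    ce[["male"]] * as.numeric(subj$sex == "male")

  em <- config$effect_matrix
  beta_col <- function(o) if (o %in% colnames(em)) em[, o] else rep(0, nf)

  # oriented unit-variance latents for the continuous end points
  latent <- function(o) {
    sys <- unname(drop(crossprod(M, beta_col(o)))) + cov_sys
    eps_sd <- sqrt(max(0.05, 1 - stats::var(sys)))
    sys + rnorm(n, 0, eps_sd)
  }
  u_mdnph <- latent("mdnph")
  u_wmh <- latent("log_wmh")
  u_atr <- latent("brain_atrophy")
  u_psmd <- latent("psmd")
  u_glob <- latent("global_cognition")
  u_exec <- latent("executive_function")
  u_speed <- latent("processing_speed")
  u_barthel <- latent("barthel_index")

  # map oriented latents (higher = worse) to raw measurement scales
  baseline <- tibble::tibble(
    subject_id = subj$subject_id,
    mdnph = 2.6 - 0.25 * u_mdnph,
    wmh_percent = clamp(exp(0.3 + 0.9 * u_wmh), 1e-4, 100),
    total_brain_volume = 1150 - 90 * u_atr,
    psmd = 3.5 + 0.8 * u_psmd,  # units 1e-4 mm^2/s
    global_cognition = -u_glob,
    executive_function = -u_exec,
    processing_speed = -u_speed,
    barthel_index = 92 - 6 * u_barthel)

  # count outcomes: presence via logistic link (planted log-odds), then a
  # Poisson-distributed number of additional lesions
  presence <- function(o, prev) {
    eta <- qlogis(prev) + unname(drop(crossprod(M, beta_col(o)))) +
      0.5 * cov_sys
    runif(n) < plogis(eta)
  }
  mb_pres <- presence("microbleed_presence", 0.35)
  lac_pres <- presence("lacune_presence", 0.45)
  baseline$microbleed_count <- ifelse(mb_pres, 1L + rpois(n, 1.2), 0L)
  baseline$lacune_count <- ifelse(lac_pres, 1L + rpois(n, 0.8), 0L)

  # Fazekas grade from the WMH latent (empirical quantile cuts so the grade
  # distribution is stable): ~55% of subjects at grade >= 2
  faz_latent <- u_wmh + rnorm(n, 0, 0.6)
  cuts <- quantile(faz_latent, c(0.12, 0.45, 0.75), names = FALSE)
  baseline$fazekas_grade <- findInterval(faz_latent, cuts)

  # dementia: exponential with log-hazard linear in planted predictors + age
  rate <- config$dementia_base_hazard *
    exp(unname(drop(crossprod(M, beta_col("dementia")))) +
          config$dementia_age_loghr * (subj$age - 65))
  t_event <- ifelse(rate > 0, rexp(n, pmax(rate, 1e-12)), Inf)
  cens <- unname(config$censor_years[subj$cohort])
  subj$dementia_event <- t_event <= cens
  subj$dementia_time <- pmin(t_event, cens)

  visits <- make_visits(config, subj, baseline)
  list(subjects = subj, visits = visits, metabolite_z = M)
}

feature_ids <- function(nf) sprintf("F%04d", seq_len(nf))

# per-outcome population annual slopes (raw units / year) and visit-level
# measurement noise SD; follow-up values = baseline + slope * t + noise
visit_dynamics <- function() {
  tibble::tribble(
    ~outcome,              ~slope,  ~slope_sd, ~noise_sd,
    "mdnph",               -0.010,  0.006,     0.03,
    "wmh_percent",          0.080,  0.050,     0.10,
    "total_brain_volume",  -5.0,    2.5,       8.0,
    "psmd",                 0.050,  0.030,     0.08,
    "global_cognition",    -0.040,  0.025,     0.10,
    "executive_function",  -0.040,  0.025,     0.10,
    "processing_speed",    -0.045,  0.025,     0.10,
    "barthel_index",       -0.400,  0.250,     1.0)
}

make_visits <- function(config, subj, baseline) {
  long_base <- tidyr::pivot_longer(baseline, -"subject_id",
                                   names_to = "outcome", values_to = "value")
  long_base$time <- 0
  if (!config$simulate_visits) {
    return(long_base[, c("subject_id", "time", "outcome", "value")])
  }
  dyn <- visit_dynamics()
  out <- list(long_base)
  for (co in names(config$n_subjects)) {
    times <- setdiff(config$visit_years[[co]], 0)
    ids <- subj$subject_id[subj$cohort == co]
    if (!length(times) || !length(ids)) next
    base_co <- baseline[match(ids, baseline$subject_id), ]
    # smooth measures: subject-specific slope around the population slope
    for (j in seq_len(nrow(dyn))) {
      o <- dyn$outcome[j]
      slope_i <- rnorm(length(ids), dyn$slope[j], dyn$slope_sd[j])
      for (t in times) {
        v <- base_co[[o]] + slope_i * t + rnorm(length(ids), 0, dyn$noise_sd[j])
        if (o == "wmh_percent") v <- clamp(v, 1e-4, 100)
        if (o == "barthel_index") v <- clamp(v, 0, 100)
        out[[length(out) + 1L]] <- tibble::tibble(
          subject_id = ids, time = t, outcome = o, value = v)
      }
    }
    # counts accumulate; Fazekas grade is carried forward
    for (o in c("microbleed_count", "lacune_count")) {
      rate <- if (o == "lacune_count") 0.06 else 0.08
      cur <- base_co[[o]]
      prev_t <- 0
      for (t in times) {
        cur <- cur + rpois(length(ids), rate * (t - prev_t))
        prev_t <- t
        out[[length(out) + 1L]] <- tibble::tibble(
          subject_id = ids, time = t, outcome = o, value = as.numeric(cur))
      }
    }
    for (t in times) {
      out[[length(out) + 1L]] <- tibble::tibble(
        subject_id = ids, time = t, outcome = "fazekas_grade",
        value = as.numeric(base_co$fazekas_grade))
    }
  }
  visits <- dplyr::arrange(dplyr::bind_rows(out), .data$subject_id,
                           .data$outcome, .data$time)
  if (config$missing_rate > 0) {
    follow <- visits$time > 0
    drop <- follow & runif(nrow(visits)) < config$missing_rate
    visits$value[drop] <- NA_real_
  }
  visits
}
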
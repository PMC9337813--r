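#' Simulate raw intensities for an analytical run
#'
#' Builds the feature-by-sample raw intensity matrix implied by a run
#' sequence and a simulated population. Study intensities are the subject's
#' biological level (lognormal around a feature base level, driven by the
#' same standardized metabolite scores used for effect planting); pooled QC
#' intensities are the feature-wise mean of all study samples; dilution QC
#' intensities scale proportionally with the dilution fraction. All samples
#' are then subjected to a smooth multiplicative within-batch drift curve,
#' per-(batch, feature) multiplicative offsets and mean-one lognormal
#' technical noise. Configurable fractions of "bad" features are planted to
#' violate each of the three feature-quality criteria.
#'
#' @param config a [sim_config()].
#' @param sequence manifest from [make_run_sequence()].
#' @param subjects result of [simulate_subjects()] (uses `metabolite_z`).
#' @return list with `raw` (an [intensity_matrix()]) and `truth`, a list
#'   holding `clean_matrix`, `drift_curve` (per-sample multiplicative
#'   factor), `batch_offsets` (features x batches), `noise_factors`,
#'   `bad_features` (per-criterion feature ids), `effect_matrix` and the
#'   seed. The identity `raw = clean * drift * offset * noise` holds exactly.
#' @export
simulate_intensities <- function(config, sequence, subjects) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  assert_that(config$tech_cv >= 0 && config$bio_cv >= 0, "negative CVs")
  set.seed(child_seed(config$seed, 3))
  M <- subjects$metabolite_z
  nf <- config$n_features
  fids <- rownames(M)
  ns <- nrow(sequence)

  base_level <- exp(rnorm(nf, log(1e5), 1))

  # planted QC violations (disjoint feature sets)
  pool <- sample(fids)
  n_bad <- function(f) min(round(f * nf), length(pool))
  take <- function(k) {
    out <- head(pool, k); pool <<- tail(pool, length(pool) - k); out
  }
  bad <- list(high_rsd = take(n_bad(config$frac_high_rsd)),
              nonlinear = take(n_bad(config$frac_nonlinear)),
              low_biovar = take(n_bad(config$frac_low_biovar)))

  bio_cv <- rep(config$bio_cv, nf)
  bio_cv[fids %in% bad$low_biovar] <- 0.01 * config$tech_cv
  tech_cv <- rep(config$tech_cv, nf)
  tech_cv[fids %in% bad$high_rsd] <- 0.60
  sb <- sqrt(log(1 + bio_cv^2))
  st <- sqrt(log(1 + tech_cv^2))

  # biological (clean) study levels
  study_clean <- base_level * exp(sb * M)   # features x subjects
  pooled_mean <- rowMeans(study_clean)

  clean <- matrix(NA_real_, nf, ns, dimnames = list(fids, sequence$sample_id))
  is_study <- sequence$sample_type == "study"
  is_qc <- sequence$sample_type == "pooled_qc"
  is_dil <- sequence$sample_type == "dilution_qc"
  clean[, is_study] <- study_clean[, sequence$subject_id[is_study]]
  clean[, is_qc] <- pooled_mean
  if (any(is_dil)) {
    fr <- sequence$dilution_fraction[is_dil]
    clean[, is_dil] <- outer(pooled_mean, fr)
    # non-linear features: flat response regardless of dilution fraction
    nl <- fids %in% bad$nonlinear
    if (any(nl)) clean[nl, is_dil] <- pooled_mean[nl] * 0.6
  }

  # smooth multiplicative drift per batch, anchored at 1 at the batch start
  drift <- rep(1, ns)
  drift_coef <- list()
  for (b in sort(unique(sequence$batch))) {
    idx <- which(sequence$batch == b)
    ro <- sequence$run_order[idx]
    tt <- (ro - min(ro)) / max(1, diff(range(ro)))
    a <- runif(2, -1, 1)
    g <- a[1] * tt + a[2] * tt^2
    mx <- max(abs(a[1] * seq(0, 1, 0.01) + a[2] * seq(0, 1, 0.01)^2))
    if (mx > 0 && config$drift_amplitude > 0) {
      drift[idx] <- 1 + config$drift_amplitude * g / mx
    }
    drift_coef[[as.character(b)]] <- a
  }

  batches <- sort(unique(sequence$batch))
  offsets <- matrix(exp(rnorm(nf * length(batches), 0, config$batch_offset_sd)),
                    nf, length(batches),
                    dimnames = list(fids, as.character(batches)))
  off_col <- offsets[, as.character(sequence$batch), drop = FALSE]

  noise <- matrix(exp(rnorm(nf * ns, 0, 1) * rep(st, ns) - rep(st^2, ns) / 2),
                  nf, ns, dimnames = dimnames(clean))

  raw <- clean * rep(drift, each = nf) * off_col * noise
  if (config$missing_rate > 0) {
    raw[runif(length(raw)) < config$missing_rate] <- NA_real_
  }

  truth <- list(clean_matrix = clean,
                drift_curve = tibble::tibble(sample_id = sequence$sample_id,
                                             batch = sequence$batch,
                                             run_order = sequence$run_order,
                                             factor = drift),
                drift_coefficients = drift_coef,
                batch_offsets = offsets,
                noise_factors = noise,
                bad_features = bad,
                effect_matrix = config$effect_matrix,
                true_event_times = subjects$subjects$dementia_time,
                seed = config$seed)
  list(raw = intensity_matrix(raw, state = "raw", platform = config$platform),
       truth = truth)
}

#' Simulate a complete study data set
#'
#' Convenience wrapper running [simulate_subjects()], [make_run_sequence()]
#' and [simulate_intensities()] from one configuration.
#'
#' @param config a [sim_config()].
#' @return list with `subjects`, `visits`, `metabolite_z`, `manifest`,
#'   `raw` (intensity matrix) and `truth`.
#' @export
simulate_dataset <- function(config) {
  pop <- simulate_subjects(config)
  manifest <- make_run_sequence(config, subject_ids = pop$subjects$subject_id)
  ints <- simulate_intensities(config, manifest, pop)
  list(subjects = pop$subjects, visits = pop$visits,
       metabolite_z = pop$metabolite_z, manifest = manifest,
       raw = ints$raw, truth = ints$truth)
}
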
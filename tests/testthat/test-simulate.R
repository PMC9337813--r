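test_that("with no drift, offsets or technical noise the raw matrix equals the clean matrix", {
  cfg <- tiny_cfg(drift_amplitude = 0, batch_offset_sd = 0, tech_cv = 0)
  sim <- simulate_dataset(cfg)
  expect_equal(as.matrix(sim$raw), sim$truth$clean_matrix, tolerance = 1e-12)
})

test_that("raw decomposes exactly into clean x drift x batch offset x noise", {
  cfg <- tiny_cfg(drift_amplitude = 0.1, batch_offset_sd = 0.1, tech_cv = 0.05)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth
  off <- tr$batch_offsets[, as.character(sim$manifest$batch), drop = FALSE]
  recon <- tr$clean_matrix *
    rep(tr$drift_curve$factor, each = nrow(tr$clean_matrix)) * off *
    tr$noise_factors
  expect_equal(as.matrix(sim$raw), recon, tolerance = 1e-12)
  # drift anchored at 1 at each batch's first injection
  first <- tapply(seq_len(nrow(sim$manifest)), sim$manifest$batch, min)
  expect_equal(tr$drift_curve$factor[first], rep(1, 2), ignore_attr = TRUE)
})

test_that("noise-free dilution samples are exactly proportional to the fraction", {
  cfg <- tiny_cfg(drift_amplitude = 0, batch_offset_sd = 0, tech_cv = 0)
  sim <- simulate_dataset(cfg)
  dil <- dilution_response(sim$raw, sim$manifest)
  expect_true(all(dil$dilution_r > 1 - 1e-12))
})

test_that("pooled-QC RSD reflects the configured technical CV", {
  # drift-free feature, tech_cv = 0.1: empirical RSD within [8, 12]%
  cfg <- sim_config(n_subjects = c(cohort_A = 150, cohort_B = 150),
                    n_features = 30, n_batches = 1, qc_interval = 5,
                    drift_amplitude = 0, batch_offset_sd = 0, tech_cv = 0.1,
                    seed = 9)
  sim <- simulate_dataset(cfg)
  man <- sim$manifest
  expect_gte(sum(man$sample_type == "pooled_qc"), 50)
  fq <- feature_quality(sim$raw, man)
  expect_true(median(fq$rsd_qc) > 8 && median(fq$rsd_qc) < 12)
  expect_true(all(fq$rsd_qc > 6.5 & fq$rsd_qc < 13.5))
})

test_that("under the global null metabolites are uncorrelated with outcomes", {
  cfg <- sim_config(n_subjects = c(cohort_A = 1000, cohort_B = 1000),
                    n_features = 5, simulate_visits = FALSE, seed = 21)
  pop <- simulate_subjects(cfg)
  base <- baseline_outcomes(pop$visits)
  for (f in 1:5) {
    for (o in c("mdnph", "global_cognition", "wmh_percent")) {
      expect_lt(abs(cor(pop$metabolite_z[f, base$subject_id], base[[o]])), 0.1)
    }
  }
})

test_that("planted linear effects surface as correlation with the oriented outcome", {
  em <- plant_effects(10, data.frame(feature = 1, endpoint = "log_wmh",
                                     beta = 0.5))
  cfg <- sim_config(n_subjects = c(cohort_A = 500, cohort_B = 500),
                    n_features = 10, effect_matrix = em,
                    simulate_visits = FALSE, seed = 5)
  pop <- simulate_subjects(cfg)
  base <- baseline_outcomes(pop$visits)
  r <- cor(pop$metabolite_z[1, base$subject_id], log(base$wmh_percent))
  expect_gt(r, 0.35)
})

test_that("zero follow-up censors everyone with no events", {
  cfg <- tiny_cfg(censor_years = c(cohort_A = 0, cohort_B = 0))
  pop <- simulate_subjects(cfg)
  expect_equal(sum(pop$subjects$dementia_event), 0)
})

test_that("event fraction matches 1 - exp(-hazard x censoring) under constant hazard", {
  h <- 0.05; cens <- 10
  cfg <- sim_config(n_subjects = c(cohort_A = 1500, cohort_B = 1500),
                    n_features = 2, dementia_base_hazard = h,
                    dementia_age_loghr = 0,
                    censor_years = c(cohort_A = cens, cohort_B = cens),
                    simulate_visits = FALSE, seed = 13)
  pop <- simulate_subjects(cfg)
  expected <- 1 - exp(-h * cens)
  se <- sqrt(expected * (1 - expected) / nrow(pop$subjects))
  expect_lt(abs(mean(pop$subjects$dementia_event) - expected), 4 * se)
})

test_that("the whole simulated data set is reproducible from config + seed", {
  a <- simulate_dataset(tiny_cfg(frac_high_rsd = 0.1))
  b <- simulate_dataset(tiny_cfg(frac_high_rsd = 0.1))
  expect_identical(as.matrix(a$raw), as.matrix(b$raw))
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$visits, b$visits)
})

test_that("negative CVs are rejected", {
  expect_error(tiny_cfg(tech_cv = -0.1), "negative")
  expect_error(tiny_cfg(bio_cv = -1), "negative")
})
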
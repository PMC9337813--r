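test_that("RSD follows its definition and flags degenerate inputs", {
  expect_equal(compute_rsd(c(5, 5, 5)), 0)
  expect_equal(compute_rsd(c(1, 2, 3)), 50)   # mean 2, sample sd 1
  expect_true(is.na(compute_rsd(c(4))))       # < 2 values
  expect_true(is.na(compute_rsd(c(0, 0))))    # mean not positive
  expect_true(is.na(compute_rsd(c(NA, 7))))   # NA-stripped single value
  # matches the scalar oracle on random vectors
  set.seed(1)
  for (i in 1:20) {
    x <- rlnorm(sample(3:30, 1))
    expect_equal(compute_rsd(x), oracle_rsd(x))
  }
})

dilution_fixture <- function(intensities) {
  fr <- c(1.0, 0.8, 0.6, 0.4, 0.2, 0.01)
  man <- tibble::tibble(
    sample_id = c(paste0("D", 1:6), "S1", "S2"),
    subject_id = c(rep(NA, 6), "a", "b"),
    sample_type = c(rep("dilution_qc", 6), "study", "study"),
    run_order = 1:8, batch = 1L,
    dilution_fraction = c(fr, NA, NA), platform = "lipid RPC+")
  m <- rbind(f1 = c(intensities, 5, 6))
  colnames(m) <- man$sample_id
  list(x = intensity_matrix(m), man = man, fr = fr)
}

test_that("dilution response reproduces the closed-form Pearson correlation", {
  fx <- dilution_fixture(c(10, 8, 6, 4, 2, 0.1))
  expect_equal(dilution_response(fx$x, fx$man)$dilution_r, 1.0)
  fx2 <- dilution_fixture(c(10, 8, 6, 4, 2, 9))
  expect_equal(dilution_response(fx2$x, fx2$man)$dilution_r,
               cor(c(10, 8, 6, 4, 2, 9), fx2$fr))
})

test_that("flat or sparse dilution responses are flagged undefined", {
  fx <- dilution_fixture(rep(7, 6))
  expect_true(is.na(dilution_response(fx$x, fx$man)$dilution_r))
  # fewer than 3 distinct fractions with data
  fx2 <- dilution_fixture(c(10, 8, NA, NA, NA, NA))
  expect_true(is.na(dilution_response(fx2$x, fx2$man)$dilution_r))
})

test_that("the three selection criteria combine as stated, with strict boundaries", {
  params <- qc_params()
  fqc <- tibble::tibble(
    feature_id = c("a", "b", "c", "d", "e"),
    rsd_qc    = c(25,  25,  0,   29.9, 30.0),
    rsd_study = c(30,  27,  5,   50,   50),
    dilution_r = c(0.9, 0.9, 1,  0.9,  0.9),
    n_qc_used = 10L, n_dilution_used = 36L, missing_study = 0)
  out <- filter_features(fqc, params)
  expect_equal(out$pass_overall, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  # b fails only the variance-ratio rule: 27 < 1.1 * 25 = 27.5
  expect_false(out$pass_variance_ratio[2])
  expect_true(out$pass_rsd_qc[2] && out$pass_dilution[2])
  # e fails the RSD rule at the boundary (strict "<")
  expect_false(out$pass_rsd_qc[5])
  expect_true(out$pass_rsd_qc[4])
  # c: constant QC passes the ratio rule vacuously strongly (5 > 0)
  expect_true(out$pass_variance_ratio[3])
})

test_that("the dilution criterion is vacuous for runs without a dilution series", {
  fqc <- tibble::tibble(feature_id = "a", rsd_qc = 10, rsd_study = 30,
                        dilution_r = NA_real_, n_qc_used = 10L,
                        n_dilution_used = 0L, missing_study = 0)
  out <- filter_features(fqc, qc_params())
  expect_true(out$pass_dilution)
  expect_true(out$pass_overall)
})

test_that("pipeline pass/fail decisions match the per-feature scalar oracle exactly", {
  cfg <- sim_config(n_subjects = c(cohort_A = 40, cohort_B = 140),
                    n_features = 150, frac_high_rsd = 0.1,
                    frac_nonlinear = 0.1, frac_low_biovar = 0.1,
                    missing_rate = 0.02, seed = 17)
  sim <- simulate_dataset(cfg)
  params <- qc_params()
  dc <- loess_drift_correct(sim$raw, sim$manifest, params)
  fqc <- filter_features(feature_quality(dc$corrected, sim$manifest, params),
                         params)
  v <- as.matrix(dc$corrected)
  oracle <- vapply(rownames(v), function(f) {
    oracle_feature_pass(v[f, ], sim$manifest, params, has_dilution = TRUE)
  }, logical(1))
  expect_equal(fqc$pass_overall, unname(oracle))
  # planted violations are reflected in the criterion failure counts
  rep <- attr(fqc, "report")
  expect_gte(rep$fail_rsd_qc, 12)
  expect_gte(rep$fail_dilution, 12)
})
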
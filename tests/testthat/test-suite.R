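suite_fixture <- function(seed = 19, n = c(cohort_A = 50, cohort_B = 150),
                          nf = 12) {
  em <- plant_effects(nf, data.frame(feature = 1:2,
                                     endpoint = c("log_wmh", "dementia"),
                                     beta = c(0.4, 0.5)))
  cfg <- sim_config(n_subjects = n, n_features = nf, effect_matrix = em,
                    seed = seed)
  pop <- simulate_subjects(cfg)
  list(cfg = cfg, pop = pop, mets = pop$metabolite_z)
}

test_that("the suite produces one q-controlled row per metabolite, outcome and spec", {
  fx <- suite_fixture()
  res <- run_analysis_suite(fx$mets, fx$pop$subjects, fx$pop$visits,
                            suite_config(adjustments = "demographic"))
  expect_true(all(table(res$analysis, res$outcome_id) %in% c(0, 12)))
  # per-family BH equals the oracle on the estimable rows
  fam <- res[res$analysis == "baseline" & res$outcome_id == "log_wmh" &
               res$estimable, ]
  expect_equal(fam$q, oracle_bh(fam$p))
  expect_true(all(res$q >= res$p, na.rm = TRUE))
  # the planted log_wmh feature is the top baseline hit
  expect_equal(fam$metabolite_id[which.min(fam$p)], "F0001")
  expect_true(all(res$ci_low <= res$effect & res$effect <= res$ci_high,
                  na.rm = TRUE))
  # both model families ran
  expect_true(all(c("linear", "logistic", "cox") %in% res$family))
})

test_that("both adjustment sets are fitted and differ", {
  fx <- suite_fixture()
  res <- run_analysis_suite(fx$mets, fx$pop$subjects, fx$pop$visits,
                            suite_config(analyses = "baseline",
                                         outcomes = "log_wmh"))
  dem <- res[res$adjustment == "demographic", ]
  ext <- res[res$adjustment == "extended", ]
  expect_equal(nrow(dem), nrow(ext))
  expect_false(identical(dem$effect, ext$effect))
})

test_that("a stratum containing all subjects reproduces the unstratified results", {
  fx <- suite_fixture()
  fx$pop$subjects$age <- pmin(fx$pop$subjects$age, 64)  # everyone < 65
  res <- run_analysis_suite(fx$mets, fx$pop$subjects, fx$pop$visits,
                            suite_config(adjustments = "demographic",
                                         analyses = "baseline",
                                         strata = c("all", "age_lt65")))
  all_s <- res[res$stratum == "all", ]
  lt <- res[res$stratum == "age_lt65", ]
  expect_equal(all_s$effect, lt$effect)
  expect_equal(all_s$p, lt$p)
  expect_equal(all_s$q, lt$q)
})

test_that("small strata are skipped with a recorded reason", {
  fx <- suite_fixture(n = c(cohort_A = 10, cohort_B = 190))
  res <- run_analysis_suite(fx$mets, fx$pop$subjects, fx$pop$visits,
                            suite_config(adjustments = "demographic",
                                         analyses = "baseline",
                                         strata = c("all", "cohort_A")))
  expect_false("cohort_A" %in% res$stratum)
  sk <- attr(res, "skipped_strata")
  expect_equal(sk$stratum, "cohort_A")
  expect_match(sk$reason, "below floor")
})

test_that("per-1-SD effects are invariant to positive rescaling of raw intensities", {
  fx <- suite_fixture()
  raw <- exp(fx$mets + 8)  # positive raw-scale intensities
  scale_to_z <- function(m) {
    t(apply(m, 1, function(x) (x - mean(x)) / sd(x)))
  }
  m1 <- scale_to_z(log(raw))
  m2 <- scale_to_z(log(raw * 137.5))
  colnames(m1) <- colnames(m2) <- colnames(fx$mets)
  cfgs <- suite_config(adjustments = "demographic", analyses = "baseline")
  r1 <- run_analysis_suite(m1, fx$pop$subjects, fx$pop$visits, cfgs)
  r2 <- run_analysis_suite(m2, fx$pop$subjects, fx$pop$visits, cfgs)
  expect_equal(r1$effect, r2$effect, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
})

test_that("flipping an outcome's orientation negates beta but not p or q", {
  fx <- suite_fixture()
  ori <- default_orientation()
  flipped <- ori
  flipped[["log_wmh"]] <- -ori[["log_wmh"]]
  cfgs <- suite_config(adjustments = "demographic", analyses = "baseline",
                       outcomes = "log_wmh")
  r1 <- run_analysis_suite(fx$mets, fx$pop$subjects, fx$pop$visits, cfgs,
                           orientation = ori)
  r2 <- run_analysis_suite(fx$mets, fx$pop$subjects, fx$pop$visits, cfgs,
                           orientation = flipped)
  expect_equal(r1$effect, -r2$effect, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
  expect_equal(r1$q, r2$q, tolerance = 1e-10)
})

test_that("an empty metabolite matrix yields an empty result, not an error", {
  fx <- suite_fixture()
  empty <- fx$mets[integer(0), , drop = FALSE]
  res <- run_analysis_suite(empty, fx$pop$subjects, fx$pop$visits)
  expect_equal(nrow(res), 0)
  expect_true(all(c("metabolite_id", "effect", "p", "q") %in% names(res)))
})

test_that("summary grid and hazard table reflect the underlying results", {
  fx <- suite_fixture()
  res <- run_analysis_suite(fx$mets, fx$pop$subjects, fx$pop$visits,
                            suite_config(adjustments = "demographic"))
  summ <- build_summary_matrix(res, "baseline", "demographic", "all")
  row <- res[res$analysis == "baseline" & res$outcome_id == "log_wmh" &
               res$metabolite_id == "F0001" & res$estimable, ]
  cell <- summ[summ$outcome_id == "log_wmh" & summ$metabolite_id == "F0001", ]
  expect_equal(cell$signed_log10_p, sign(row$effect) * -log10(row$p))
  expect_equal(cell$sig_p, row$p < 0.05)
  expect_equal(cell$sig_q, row$q < 0.05)
  expect_equal(cell$stars,
               if (row$q < 0.05) "**" else if (row$p < 0.05) "*" else "")
  # requesting an absent spec names the available ones
  expect_error(build_summary_matrix(res, "baseline", "extended", "all"),
               "available")
  hz <- build_hazard_table(res, "demographic", "all")
  cox <- res[res$family == "cox" & res$estimable, ]
  expect_equal(hz$hr, exp(cox$effect[order(cox$p)]))
  expect_equal(hz$p, sort(cox$p))
  # null log HR maps to HR 1 with a log-symmetric CI
  lh <- build_hazard_table(tibble::tibble(
    metabolite_id = "m", outcome_id = "dementia", analysis = "dementia",
    family = "cox", adjustment = "demographic", stratum = "all",
    n_used = 100L, effect = 0, se = 0.1,
    ci_low = -qnorm(0.975) * 0.1, ci_high = qnorm(0.975) * 0.1,
    p = 1, q = 1, estimable = TRUE, reason = ""))
  expect_equal(lh$hr, 1)
  expect_equal(lh$hr_low * lh$hr_high, 1, tolerance = 1e-12)
})
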
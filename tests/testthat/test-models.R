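fit_fixture <- function(seed = 2, n = 400, beta = 0.4) {
  set.seed(seed)
  covs <- data.frame(cohort = factor(sample(c("A", "B"), n, TRUE)),
                     age = rnorm(n, 66, 9),
                     sex = factor(sample(c("m", "f"), n, TRUE)))
  met <- rnorm(n)
  y <- beta * met + 0.02 * covs$age + 0.3 * (covs$cohort == "B") + rnorm(n)
  list(met = met, y = y, covs = covs)
}

test_that("the linear fit reproduces the lm() metabolite coefficient", {
  fx <- fit_fixture()
  res <- fit_metabolite_outcome(fx$met, fx$y, fx$covs, "linear")
  ref <- summary(lm(fx$y ~ fx$met + cohort + age + sex, data = fx$covs))
  expect_equal(res$effect, unname(ref$coefficients["fx$met", 1]))
  expect_equal(res$se, unname(ref$coefficients["fx$met", 2]))
  expect_equal(res$p, unname(ref$coefficients["fx$met", 4]))
  expect_true(res$estimable)
  expect_equal(res$n_used, 400L)
  expect_equal(res$ci_low, res$effect - qnorm(0.975) * res$se)
})

test_that("the logistic fit reproduces the glm() metabolite coefficient", {
  fx <- fit_fixture()
  yb <- runif(length(fx$y)) < plogis(-0.5 + 0.5 * fx$met)
  res <- fit_metabolite_outcome(fx$met, yb, fx$covs, "logistic")
  ref <- summary(glm(yb ~ fx$met + cohort + age + sex, data = fx$covs,
                     family = binomial()))
  expect_equal(res$effect, unname(ref$coefficients["fx$met", 1]))
  expect_equal(res$p, unname(ref$coefficients["fx$met", 4]))
})

test_that("a metabolite collinear with a covariate is flagged non-estimable", {
  fx <- fit_fixture()
  res <- fit_metabolite_outcome(fx$covs$age, fx$y, fx$covs, "linear")
  expect_false(res$estimable)
  expect_match(res$reason, "collinear")
  expect_true(is.na(res$effect))
})

test_that("missing values reduce n_used via complete-case analysis", {
  fx <- fit_fixture()
  fx$met[1:25] <- NA
  res <- fit_metabolite_outcome(fx$met, fx$y, fx$covs, "linear")
  expect_equal(res$n_used, 375L)
})

test_that("the fast matrix path equals per-metabolite lm fits exactly", {
  fx <- fit_fixture()
  set.seed(6)
  M <- matrix(rnorm(400 * 8), 400, 8, dimnames = list(NULL, paste0("f", 1:8)))
  C <- model.matrix(~ ., fx$covs)[, -1]
  fast <- metabosvd:::linear_assoc_matrix(M, fx$y, C)
  for (j in 1:8) {
    ref <- summary(lm(fx$y ~ M[, j] + C))$coefficients[2, ]
    expect_equal(fast$effect[j], unname(ref[1]), tolerance = 1e-10)
    expect_equal(fast$se[j], unname(ref[2]), tolerance = 1e-10)
    expect_equal(fast$p[j], unname(ref[4]), tolerance = 1e-10)
  }
})

test_that("the Cox fit recovers a planted hazard and handles degenerate designs", {
  set.seed(11)
  n <- 800
  covs <- data.frame(age = rnorm(n, 66, 9))
  met <- rnorm(n)
  t_ev <- rexp(n, 0.04 * exp(0.4 * met))
  time <- pmin(t_ev, 10); event <- t_ev <= 10
  res <- fit_dementia_cox(met, time, event, covs)
  expect_true(res$estimable)
  expect_lt(abs(res$effect - 0.4), 3 * res$se)
  ref <- survival::coxph(survival::Surv(time, event) ~ met + age,
                         data = covs, ties = "efron")
  expect_equal(res$effect, unname(coef(ref)["met"]), tolerance = 1e-8)
  # zero events: hard error
  expect_error(fit_dementia_cox(met, rep(0.001, n), rep(FALSE, n), covs),
               "no events")
  # below the event floor: flagged, not an error
  few <- rep(FALSE, n); few[1:5] <- TRUE
  res2 <- fit_dementia_cox(met, time, few, covs, min_events = 10)
  expect_false(res2$estimable)
  expect_match(res2$reason, "5 events")
})

test_that("a null metabolite gives a log hazard ratio centred at zero", {
  set.seed(12)
  est <- replicate(120, {
    n <- 300
    met <- rnorm(n)
    t_ev <- rexp(n, 0.05)
    fit_dementia_cox(met, pmin(t_ev, 10), t_ev <= 10,
                     data.frame(age = rnorm(n, 65, 9)))$effect
  })
  expect_lt(abs(mean(est)), 0.05)
})

test_that("BH q-values match the step-up oracle exactly", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(7)
  for (i in 1:25) {
    m <- sample(1:200, 1)
    p <- runif(m)
    if (i %% 3 == 0) p <- round(p, 1)  # exercise ties
    expect_identical(bh_fdr(p), oracle_bh(p))
  }
})

test_that("q is monotone in p, bounded below by p, and NA-tolerant", {
  set.seed(8)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
  # NA entries are excluded from the family, not counted in m
  p2 <- c(0.01, NA, 0.04)
  expect_equal(bh_fdr(p2), c(0.02, NA, 0.04))
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
  expect_error(bh_fdr(c(-0.1)), "outside")
})
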
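# The natural-effect formulas are exercised first on hand-built fits with
# chosen coefficients (expected values computed independently by hand),
# then against the counterfactual Monte-Carlo oracle and the bootstrap.

spec_no_int <- function(a = 1, a_star = 0, c_cond = c(0, 0)) {
  mediation_spec(a, a_star, interaction = FALSE, c_cond = c_cond)
}

test_that("severed paths give null effects", {
  # no mediator effect on outcome: NIE is null, NDE carries theta1
  med <- fake_med_fit(0, 0.002)
  out <- fake_out_fit(-2, 0.05, 0)
  pt <- natural_effects(med, out, spec_no_int())
  expect_equal(exp(pt$log_nde), exp(0.05))
  expect_equal(exp(pt$log_nie), 1)

  # no exposure effect on mediator: NIE null regardless of theta2
  pt2 <- natural_effects(fake_med_fit(0.1, 0), fake_out_fit(-2, 0.02, 5),
                         spec_no_int())
  expect_equal(exp(pt2$log_nie), 1)
})

test_that("interaction-free effects match the hand-computed products", {
  med <- fake_med_fit(0, 0.002)
  out <- fake_out_fit(-2, 0.02, 5)
  pt <- natural_effects(med, out, spec_no_int())
  expect_equal(pt$log_nie, 0.01)
  expect_equal(exp(pt$log_nie), 1.01005, tolerance = 1e-5)
  expect_equal(pt$log_nde, 0.02)
  expect_equal(pt$log_te, 0.03)
})

test_that("interaction formula reproduces an independent hand evaluation", {
  # theta3 = 0.1, sigma2 = 0.0025, a* = 50 -> a = 51, c = 0:
  # lin  = 0.01 + 0.002*50 + 1.0*0.0025              = 0.1125
  # NDE  = (0.02 + 0.1*0.1125) + 0.5*0.01*0.0025*101 = 0.0325125
  # NIE  = 0.002*(1.0 + 0.1*51)                      = 0.0122
  med <- fake_med_fit(0.01, 0.002, sigma2 = 0.0025)
  out <- fake_out_fit(-3, 0.02, 1.0, theta3 = 0.1)
  sp <- mediation_spec(51, 50, interaction = TRUE, c_cond = c(0, 0))
  pt <- natural_effects(med, out, sp)
  expect_equal(pt$log_nde, 0.0325125, tolerance = 1e-12)
  expect_equal(pt$log_nie, 0.0122, tolerance = 1e-12)
})

test_that("interaction flag must match the fitted model", {
  med <- fake_med_fit(0, 0.002)
  out_plain <- fake_out_fit(-2, 0.02, 5)
  out_int <- fake_out_fit(-2, 0.02, 5, theta3 = 0.01)
  sp_int <- mediation_spec(1, 0, interaction = TRUE, c_cond = c(0, 0))
  expect_error(natural_effects(med, out_plain, sp_int), "without")
  expect_error(natural_effects(med, out_int, spec_no_int()), "refit")
})

test_that("the TE = NDE + NIE identity holds to machine precision on real fits", {
  for (seed in 1:6) {
    p <- sim_params(n = 500, target_prevalence = 0.3, seed = seed)
    cohort <- suppressWarnings(simulate_cohort(p))
    for (interaction in c(FALSE, TRUE)) {
      fit <- suppressWarnings(
        mediate_age_frailty(cohort, "composite", interaction = interaction))
      est <- fit$estimates
      expect_equal(est$log_or[est$term == "total_effect"],
                   est$log_or[est$term == "natural_direct"] +
                     est$log_or[est$term == "natural_indirect"],
                   tolerance = 1e-14)
    }
  }
})

test_that("without interaction the estimates ignore the conditioning vector", {
  p <- sim_params(n = 800, target_prevalence = 0.2, seed = 3)
  cohort <- suppressWarnings(simulate_cohort(p))
  f1 <- suppressWarnings(
    mediate_age_frailty(cohort, "composite", c_cond = rep(0, 5)))
  f2 <- suppressWarnings(
    mediate_age_frailty(cohort, "composite", c_cond = c(1, 1, 0, 1, 20)))
  expect_equal(f1$estimates$log_or, f2$estimates$log_or)
  expect_equal(f1$estimates$se, f2$estimates$se)
})

test_that("delta-method SE reduces to the product form without interaction", {
  v_b1 <- 0.0004^2
  v_t2 <- 0.8^2
  vb <- diag(c(0, v_b1, 0, 0))
  vt <- diag(c(0, 0, v_t2, 0, 0))
  med <- fake_med_fit(0, 0.002, beta2 = c(a = 0, b = 0), vcov = vb)
  out <- fake_out_fit(-2, 0.02, 5, theta4 = c(a = 0, b = 0), vcov = vt)
  sp <- mediation_spec(10, 8, interaction = FALSE, c_cond = c(0, 0))
  se <- delta_method_se(med, out, sp)
  expect_equal(se$se_nie,
               sqrt(5^2 * v_b1 + 0.002^2 * v_t2) * 2, tolerance = 1e-12)
  expect_equal(se$se_nde, sqrt(0) * 2)

  # zero covariance collapses all SEs
  med0 <- fake_med_fit(0, 0.002, beta2 = c(a = 0, b = 0))
  out0 <- fake_out_fit(-2, 0.02, 5, theta4 = c(a = 0, b = 0))
  se0 <- delta_method_se(med0, out0, sp)
  expect_equal(c(se0$se_te, se0$se_nde, se0$se_nie), c(0, 0, 0))
})

test_that("proportion mediated follows the odds-ratio-scale formula", {
  expect_equal(proportion_mediated(1.5, 1), 0)
  expect_equal(proportion_mediated(1, 1.3), 1)
  expect_equal(proportion_mediated(1.02, 1.01),
               1.02 * 0.01 / (1.02 * 1.01 - 1), tolerance = 1e-12)
  expect_equal(proportion_mediated(1.02, 1.01), 0.3377, tolerance = 1e-3)
  expect_error(proportion_mediated(2, 0.5), "undefined")
})

test_that("PM inference matches a finite-difference gradient", {
  d <- log(1.02); i <- log(1.01)
  Sigma <- matrix(c(1e-4, 2e-5, 2e-5, 4e-5), 2, 2)
  inf <- pm_inference(d, i, Sigma)

  pm_fun <- function(dd, ii) {
    exp(dd) * (exp(ii) - 1) / (exp(dd + ii) - 1)
  }
  h <- 1e-7
  g <- c((pm_fun(d + h, i) - pm_fun(d - h, i)) / (2 * h),
         (pm_fun(d, i + h) - pm_fun(d, i - h)) / (2 * h))
  se_num <- sqrt(drop(crossprod(g, Sigma %*% g)))
  expect_equal(inf$se, se_num, tolerance = 1e-6)
  expect_equal(inf$pm, pm_fun(d, i), tolerance = 1e-12)
  expect_true(inf$ci_lo_raw <= inf$pm && inf$pm <= inf$ci_hi_raw)
  expect_gte(inf$ci_lo, 0)
  expect_lte(inf$ci_hi, 1)

  collapsed <- pm_inference(d, i, matrix(0, 2, 2))
  expect_equal(collapsed$ci_lo_raw, collapsed$pm)
  expect_equal(collapsed$ci_hi_raw, collapsed$pm)
})

test_that("formula estimands agree with the Monte-Carlo counterfactual oracle", {
  p <- rare_params(target_prevalence = 0.02)
  cc <- expected_covariates(p)
  a_star <- p$age_mean; a <- a_star + 1
  mc <- true_effects(p, a = a, a_star = a_star, c_cond = cc,
                     n_mc = 2e5, seed = 8)
  ft <- formula_truth(p, a, a_star, cc)
  expect_lt(abs(ft$log_nie - log(mc$or_nie)), 3 * mc$se_log_nie)
  expect_lt(abs(ft$log_nde - log(mc$or_nde)), 3 * mc$se_log_nde)
})

test_that("bootstrap intervals are seed-deterministic and leave the RNG alone", {
  p <- rare_params(n = 400, target_prevalence = 0.1)
  cohort <- simulate_cohort(p, seed = 12)
  set.seed(2024)
  before <- .Random.seed
  b1 <- bootstrap_mediation(cohort, "death", B = 200, seed = 5)
  expect_identical(.Random.seed, before)
  b2 <- bootstrap_mediation(cohort, "death", B = 200, seed = 5)
  expect_identical(b1$ci, b2$ci)
  expect_lte(b1$n_dropped, 20)
  expect_error(bootstrap_mediation(cohort, "death", B = 100, seed = 1),
               "B >= 200")
})

test_that("bootstrap NIE interval covers the null when no mediation exists", {
  p <- rare_params(n = 2000, beta1 = 0, theta2 = 0,
                   target_prevalence = 0.1)
  cohort <- simulate_cohort(p, seed = 30)
  b <- bootstrap_mediation(cohort, "death", B = 200, seed = 31)
  nie <- b$ci[b$ci$term == "natural_indirect", ]
  expect_lte(nie$lo, 1)
  expect_gte(nie$hi, 1)
})

test_that("interaction test reports Wald, LR and effect shifts", {
  p <- rare_params(n = 1500, target_prevalence = 0.1)
  cohort <- simulate_cohort(p, seed = 17)
  it <- test_interaction(cohort, "death")
  expect_true(it$wald$p >= 0 && it$wald$p <= 1)
  expect_equal(it$lr$df, 1)
  expect_equal(it$effect_deltas$delta,
               it$effect_deltas$with_interaction -
                 it$effect_deltas$without_interaction)
})

test_that("high prevalence raises the rare-outcome warning", {
  p <- sim_params(n = 500, seed = 2)
  cohort <- simulate_cohort(p)
  expect_warning(mediate_age_frailty(cohort, "composite"),
                 class = "frailtymed_prevalence_warning")
})
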
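# Shared fixtures: hand-built model "fits" with chosen coefficients (for
# exercising the mediation formulas without data), small cohort builders,
# and the rare-outcome generative scenarios used by the validation suite.

# Mediator fit with chosen coefficients; zero covariance unless supplied.
fake_med_fit <- function(beta0, beta1, beta2 = c(0, 0), sigma2 = 0,
                         vcov = NULL) {
  coef <- c(`(Intercept)` = beta0, age = beta1, beta2)
  if (is.null(vcov)) vcov <- matrix(0, length(coef), length(coef))
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2,
                 sigma2 = sigma2, vcov = vcov, coef = coef,
                 n = NA_integer_),
            class = "mediator_fit")
}

fake_out_fit <- function(theta0, theta1, theta2, theta3 = NULL,
                         theta4 = c(0, 0), vcov = NULL) {
  interaction <- !is.null(theta3)
  coef <- c(`(Intercept)` = theta0, age = theta1, fi = theta2)
  if (interaction) coef <- c(coef, `age:fi` = theta3)
  coef <- c(coef, theta4)
  if (is.null(vcov)) vcov <- matrix(0, length(coef), length(coef))
  structure(list(theta0 = theta0, theta1 = theta1, theta2 = theta2,
                 theta3 = if (interaction) theta3 else 0,
                 theta4 = theta4, vcov = vcov, coef = coef,
                 loglik = NA_real_, converged = TRUE,
                 interaction = interaction, n = NA_integer_),
            class = "outcome_fit")
}

# Rare-outcome generative truth used across the validation experiments:
# mediator mean ~0.30 (no clipping), 8% mortality, no interaction.
rare_params <- function(n = 292, theta3 = 0, target_prevalence = 0.08,
                        ...) {
  sim_params(n = n, outcome_scenario = "death", beta0 = 0.165,
             sigma = 0.05, theta3 = theta3,
             target_prevalence = target_prevalence, ...)
}

# Expected covariate values under sim_params defaults, matching the
# conditioning vector recovery_experiment and true_effects use.
expected_covariates <- function(p) {
  u <- (seq_len(1e5) - 0.5) / 1e5
  nihss_mean <- mean(pmin(pmax(round(exp(
    qnorm(u) * p$nihss_sdlog + p$nihss_meanlog)), 0), 42))
  c(sex_male = p$p_male, race_white = p$p_white,
    smoking_former = p$smoking_probs[2],
    smoking_current = p$smoking_probs[3], nihss = nihss_mean)
}

# Closed-form natural-effect estimands at the generative coefficients.
formula_truth <- function(p, a, a_star, c_cond) {
  med <- fake_med_fit(p$beta0, p$beta1, p$beta2, sigma2 = p$sigma^2)
  out <- fake_out_fit(p$theta0, p$theta1, p$theta2,
                      theta3 = if (p$theta3 != 0) p$theta3,
                      theta4 = p$theta4)
  sp <- mediation_spec(a, a_star, interaction = p$theta3 != 0,
                       c_cond = c_cond)
  natural_effects(med, out, sp)
}

# Write a small cohort CSV (3 deficit columns get appended as all-absent
# unless a full schema is in play).
write_cohort_csv <- function(df, path = withr::local_tempfile(
                               fileext = ".csv",
                               .local_envir = parent.frame())) {
  readr::write_csv(df, path, progress = FALSE)
  path
}

toy_schema <- function(k = 31) deficit_schema(paste0("item", seq_len(k)))

# Minimal raw cohort data frame with k all-absent deficits.
toy_raw_cohort <- function(n = 3, k = 31) {
  df <- data.frame(
    id = as.character(seq_len(n)),
    age = seq(60, by = 5, length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    race = rep(c("white", "black"), length.out = n),
    smoking = rep(c("never", "former", "current"), length.out = n),
    nihss = rep(c(4, 12, 20), length.out = n),
    mrs_90d = rep(c(1, 3, 6), length.out = n)
  )
  for (j in seq_len(k)) df[[paste0("def_item", j)]] <- 0
  df
}
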
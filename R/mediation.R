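# Regression-based causal mediation for a continuous mediator (frailty
# index, linear model) and a binary outcome (logistic model), under the
# rare-outcome approximation. Natural-effect log odds ratios are closed
# forms in the two models' coefficients; uncertainty comes from the delta
# method (the two coefficient blocks treated as independent, the mediator
# residual variance treated as fixed) or a participant-level bootstrap.

# Run code with a local RNG state; the caller's stream is untouched.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specify the exposure contrast for the mediation estimands
#'
#' Natural effects are defined for a change of the exposure (age) from a
#' reference level `a_star` to a comparison level `a`. The default
#' contrast is one year upward from the sample mean age, so odds ratios
#' read "per additional year of age". The covariate conditioning vector
#' `c_cond` only enters the formulas when the exposure-mediator
#' interaction is included; it defaults to the covariate sample means.
#'
#' @param a,a_star Comparison and reference exposure levels, in years.
#' @param interaction Does the outcome model include the age-by-frailty
#'   product term?
#' @param c_cond Numeric vector of covariate values at which effects are
#'   conditioned (length = number of covariates).
#' @param conf_level Confidence level for intervals (default 0.95).
#' @return A list of class `mediation_spec`.
#' @export
mediation_spec <- function(a, a_star, interaction = FALSE, c_cond = NULL,
                           conf_level = 0.95) {
  stopifnot(is.numeric(a), is.numeric(a_star), a != a_star,
            conf_level > 0, conf_level < 1)
  structure(list(a = a, a_star = a_star, interaction = interaction,
                 c_cond = c_cond, conf_level = conf_level),
            class = "mediation_spec")
}

.check_spec_fit <- function(spec, out) {
  if (spec$interaction && !out$interaction) {
    stop("spec requests the exposure-mediator interaction but the outcome ",
         "model was fitted without it", call. = FALSE)
  }
  if (!spec$interaction && out$interaction) {
    stop("outcome model includes the interaction term but the spec sets ",
         "interaction = FALSE; refit without it", call. = FALSE)
  }
}

#' Natural-effect log odds ratios from the two fitted models
#'
#' Combines the linear mediator fit (coefficients beta, residual variance
#' sigma^2) and the logistic outcome fit (coefficients theta) into the
#' natural direct, natural indirect and total effect of moving the
#' exposure from `a_star` to `a`, on the log odds-ratio scale:
#' \deqn{\log OR^{NDE} = [\theta_1 + \theta_3(\beta_0 + \beta_1 a^* +
#'   \beta_2' c + \theta_2\sigma^2)](a - a^*) +
#'   \tfrac12\theta_3^2\sigma^2(a^2 - a^{*2})}
#' \deqn{\log OR^{NIE} = (\theta_2\beta_1 + \theta_3\beta_1 a)(a - a^*)}
#' with \eqn{\log OR^{TE} = \log OR^{NDE} + \log OR^{NIE}} by
#' construction. Without the interaction (\eqn{\theta_3 = 0}) these reduce
#' to \eqn{\theta_1(a - a^*)} and \eqn{\theta_2\beta_1(a - a^*)} and do
#' not depend on the covariate conditioning values. The formulas rest on
#' the rare-outcome approximation; accuracy degrades as outcome
#' prevalence rises.
#'
#' @param med A `mediator_fit`.
#' @param out An `outcome_fit`.
#' @param spec A `mediation_spec`; its `interaction` flag must match the
#'   outcome fit.
#' @return A list with `log_nde`, `log_nie`, `log_te`.
#' @export
natural_effects <- function(med, out, spec) {
  .check_spec_fit(spec, out)
  c_cond <- spec$c_cond %||% rep(0, length(med$beta2))
  stopifnot(length(c_cond) == length(med$beta2))
  d <- spec$a - spec$a_star
  q <- spec$a^2 - spec$a_star^2
  lin <- med$beta0 + med$beta1 * spec$a_star + sum(med$beta2 * c_cond) +
    out$theta2 * med$sigma2
  log_nde <- (out$theta1 + out$theta3 * lin) * d +
    0.5 * out$theta3^2 * med$sigma2 * q
  log_nie <- (out$theta2 * med$beta1 + out$theta3 * med$beta1 * spec$a) * d
  list(log_nde = log_nde, log_nie = log_nie, log_te = log_nde + log_nie)
}

# Gradients of the natural-effect log-ORs in the stacked coefficient
# vector (beta block then theta block), sigma^2 held fixed.
.ne_gradients <- function(med, out, spec) {
  c_cond <- spec$c_cond %||% rep(0, length(med$beta2))
  d <- spec$a - spec$a_star
  q <- spec$a^2 - spec$a_star^2
  th3 <- out$theta3
  lin <- med$beta0 + med$beta1 * spec$a_star + sum(med$beta2 * c_cond) +
    out$theta2 * med$sigma2
  kb <- length(med$coef)      # (Intercept), age, covariates
  kt <- length(out$coef)

  g_nde_b <- c(th3 * d, th3 * spec$a_star * d, th3 * c_cond * d)
  g_nie_b <- c(0, (out$theta2 + th3 * spec$a) * d, rep(0, length(c_cond)))
  stopifnot(length(g_nde_b) == kb)

  # theta block order: intercept, age, fi, [age:fi], covariates
  g_nde_t <- numeric(kt); g_nie_t <- numeric(kt)
  g_nde_t[2] <- d
  g_nde_t[3] <- th3 * med$sigma2 * d
  g_nie_t[3] <- med$beta1 * d
  if (out$interaction) {
    g_nde_t[4] <- lin * d + th3 * med$sigma2 * q
    g_nie_t[4] <- med$beta1 * spec$a * d
  }
  list(nde = c(g_nde_b, g_nde_t), nie = c(g_nie_b, g_nie_t))
}

#' Delta-method standard errors for the natural effects
#'
#' First-order propagation of the two models' coefficient covariance
#' matrices (stacked block-diagonally, i.e. the fits treated as
#' independent) through the natural-effect formulas. The mediator residual
#' variance is treated as fixed. The joint 2x2 covariance of
#' (log NDE, log NIE) is retained because proportion-mediated inference
#' needs it; the total-effect variance follows from the sum.
#'
#' @inheritParams natural_effects
#' @return A list with `se_nde`, `se_nie`, `se_te`, and `cov` (the 2x2
#'   covariance of the log NDE and log NIE estimates).
#' @export
delta_method_se <- function(med, out, spec) {
  .check_spec_fit(spec, out)
  V <- matrix(0, nrow = length(med$coef) + length(out$coef),
              ncol = length(med$coef) + length(out$coef))
  ib <- seq_along(med$coef)
  it <- length(med$coef) + seq_along(out$coef)
  V[ib, ib] <- med$vcov
  V[it, it] <- out$vcov
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("coefficient covariance matrix is not positive semi-definite",
         call. = FALSE)
  }
  g <- .ne_gradients(med, out, spec)
  v_nde <- drop(crossprod(g$nde, V %*% g$nde))
  v_nie <- drop(crossprod(g$nie, V %*% g$nie))
  cv <- drop(crossprod(g$nde, V %*% g$nie))
  cov2 <- matrix(c(v_nde, cv, cv, v_nie), 2, 2,
                 dimnames = list(c("log_nde", "log_nie"),
                                 c("log_nde", "log_nie")))
  list(se_nde = sqrt(v_nde), se_nie = sqrt(v_nie),
       se_te = sqrt(v_nde + v_nie + 2 * cv), cov = cov2)
}

#' Proportion mediated on the odds-ratio scale
#'
#' For a binary outcome the share of the total effect transmitted through
#' the mediator is
#' \deqn{PM = \frac{OR^{NDE}(OR^{NIE} - 1)}{OR^{NDE} OR^{NIE} - 1},}
#' not the naive ratio of log odds ratios. PM is 0 when the indirect-path
#' odds ratio is 1 and 1 when the direct-path odds ratio is 1; it is
#' undefined when the total effect is null.
#'
#' @param or_nde,or_nie Natural direct and indirect effect odds ratios.
#' @return The proportion mediated (a scalar; can fall outside \[0, 1\]
#'   when direct and indirect effects point in opposite directions).
#' @export
#' @examples
#' proportion_mediated(1.02, 1.01)
proportion_mediated <- function(or_nde, or_nie) {
  if (abs(or_nde * or_nie - 1) < 1e-12) {
    stop("total effect odds ratio is 1; proportion mediated is undefined",
         call. = FALSE)
  }
  or_nde * (or_nie - 1) / (or_nde * or_nie - 1)
}

#' Delta-method inference for the proportion mediated
#'
#' Propagates the joint covariance of (log NDE, log NIE) through the
#' proportion-mediated formula. Writing d = log NDE, i = log NIE,
#' T = exp(d + i), the gradient is
#' dPM/dd = -(T - e^d)/(T - 1)^2 and dPM/di = T(e^d - 1)/(T - 1)^2.
#' The reported interval is truncated to \[0, 1\] (a proportion), while
#' the raw interval is retained; the p-value tests PM = 0.
#'
#' @param log_nde,log_nie Log odds-ratio point estimates.
#' @param cov 2x2 covariance of (log_nde, log_nie) from
#'   [delta_method_se()].
#' @param conf_level Confidence level.
#' @return A list with `pm`, `se`, `ci_lo`, `ci_hi` (truncated),
#'   `ci_lo_raw`, `ci_hi_raw`, and `p`.
#' @export
pm_inference <- function(log_nde, log_nie, cov, conf_level = 0.95) {
  stopifnot(is.matrix(cov), all(dim(cov) == c(2, 2)))
  if (any(!is.finite(cov))) stop("degenerate covariance", call. = FALSE)
  pm <- proportion_mediated(exp(log_nde), exp(log_nie))
  tt <- exp(log_nde + log_nie)
  dd <- (tt - 1)^2
  grad <- c(-(tt - exp(log_nde)) / dd, tt * (exp(log_nde) - 1) / dd)
  v <- drop(crossprod(grad, cov %*% grad))
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- pm - z * se
  hi <- pm + z * se
  p <- if (se == 0) as.numeric(pm != 0) else 2 * stats::pnorm(-abs(pm / se))
  list(pm = pm, se = se,
       ci_lo = min(max(lo, 0), 1), ci_hi = min(max(hi, 0), 1),
       ci_lo_raw = lo, ci_hi_raw = hi, p = p)
}

#' Estimate how much of the age effect on a stroke outcome is mediated by
#' frailty
#'
#' The high-level analysis: takes a complete-case-ready cohort, fits the
#' linear frailty-on-age regression and the logistic outcome regression
#' (both adjusted for sex, race, admission NIHSS and smoking status),
#' screens the designs for multicollinearity (VIF > 3 warns), and returns
#' total, natural direct and natural indirect effect odds ratios with
#' delta-method confidence intervals plus the proportion mediated.
#' Records with a missing value in any model variable are dropped first
#' (complete-case analysis; exclusions are reported on the object). A
#' classed warning is raised when outcome prevalence exceeds 10%, where
#' the rare-outcome odds-ratio approximation begins to strain.
#'
#' @param data Cohort tibble with `age`, `sex`, `race`, `smoking`,
#'   `nihss`, `fi` and the outcome column (see [add_outcomes()],
#'   [add_frailty_index()]).
#' @param outcome `"composite"` (mRS > 2) or `"death"`.
#' @param interaction Include the age-by-frailty interaction in the
#'   outcome model?
#' @param a,a_star Exposure contrast in years; defaults to sample mean age
#'   + 1 vs sample mean age.
#' @param c_cond Covariate conditioning values (defaults to sample means;
#'   only matters with `interaction = TRUE`).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `fi_mediation` with `estimates` (a tibble of
#'   TE/NDE/NIE rows), `pm` (proportion-mediated inference),
#'   `mediator_fit`, `outcome_fit`, `spec`, `vif`, `prevalence`, `n`,
#'   `dropped`. Methods: [tidy()][generics::tidy],
#'   [glance()][generics::glance], `autoplot()`, `print()`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_params(n = 400, seed = 7))
#' fit <- mediate_age_frailty(cohort, outcome = "composite")
#' generics::tidy(fit)
mediate_age_frailty <- function(data, outcome = c("composite", "death"),
                                interaction = FALSE, a = NULL, a_star = NULL,
                                c_cond = NULL, conf_level = 0.95) {
  outcome <- match.arg(outcome)
  required <- c("age", "sex", "race", "smoking", "nihss", "fi", outcome)
  cc <- complete_cases(data, required)
  design <- encode_design(cc$data, outcome)

  prevalence <- mean(design$y)
  if (prevalence > 0.10) {
    rlang::warn(
      sprintf(paste0("outcome prevalence is %.1f%%; the rare-outcome ",
                     "odds-ratio approximation may be strained"),
              100 * prevalence),
      class = "frailtymed_prevalence_warning")
  }

  med <- fit_mediator_model(design)
  out <- fit_outcome_model(design, interaction = interaction)
  vifs <- vif(design)
  if (any(vifs > 3)) {
    rlang::warn(
      paste0("variance inflation above 3 for: ",
             paste(names(vifs)[vifs > 3], collapse = ", ")),
      class = "frailtymed_vif_warning")
  }

  a_star <- a_star %||% mean(design$exposure)
  a <- a %||% (a_star + 1)
  c_cond <- c_cond %||% colMeans(design$covariates)
  spec <- mediation_spec(a = a, a_star = a_star, interaction = interaction,
                         c_cond = c_cond, conf_level = conf_level)

  pt <- natural_effects(med, out, spec)
  se <- delta_method_se(med, out, spec)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- tibble::tibble(
    term = c("total_effect", "natural_direct", "natural_indirect"),
    log_or = c(pt$log_te, pt$log_nde, pt$log_nie),
    se = c(se$se_te, se$se_nde, se$se_nie)
  )
  est <- dplyr::mutate(
    est,
    or = exp(.data$log_or),
    ci_lo = exp(.data$log_or - z * .data$se),
    ci_hi = exp(.data$log_or + z * .data$se),
    p = 2 * stats::pnorm(-abs(.data$log_or / .data$se))
  )
  pm <- pm_inference(pt$log_nde, pt$log_nie, se$cov, conf_level)

  structure(
    list(estimates = est, pm = pm, mediator_fit = med, outcome_fit = out,
         spec = spec, vif = vifs, prevalence = prevalence,
         n = length(design$y), outcome = outcome, dropped = cc$dropped,
         ne_cov = se$cov),
    class = "fi_mediation"
  )
}

#' @export
print.fi_mediation <- function(x, ...) {
  cat(sprintf(
    "Age -> frailty -> %s mediation (n = %d, prevalence %.1f%%)\n",
    x$outcome, x$n, 100 * x$prevalence))
  cat(sprintf("Exposure contrast: age %.1f vs %.1f years%s\n",
              x$spec$a, x$spec$a_star,
              if (x$spec$interaction) " (with age x frailty interaction)"
              else ""))
  est <- x$estimates
  for (i in seq_len(nrow(est))) {
    cat(sprintf("  %-17s OR %.3f (%.3f-%.3f), p = %.3g\n",
                est$term[i], est$or[i], est$ci_lo[i], est$ci_hi[i],
                est$p[i]))
  }
  cat(sprintf("  %-17s %.1f%% (%.1f%%-%.1f%%), p = %.3g\n",
              "prop. mediated", 100 * x$pm$pm, 100 * x$pm$ci_lo,
              100 * x$pm$ci_hi, x$pm$p))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mediation fit
#'
#' One row per estimand (total, natural direct, natural indirect,
#' proportion mediated) with point estimate, confidence bounds and
#' p-value. Odds-ratio rows carry `estimate = OR`; the proportion-mediated
#' row carries the proportion itself with its \[0, 1\]-truncated interval.
#'
#' @param x An `fi_mediation` object.
#' @param ... Unused.
#' @method tidy fi_mediation
#' @export
tidy.fi_mediation <- function(x, ...) {
  or_rows <- tibble::tibble(
    term = x$estimates$term,
    estimate = x$estimates$or,
    std.error = x$estimates$se,
    conf.low = x$estimates$ci_lo,
    conf.high = x$estimates$ci_hi,
    p.value = x$estimates$p
  )
  pm_row <- tibble::tibble(
    term = "proportion_mediated",
    estimate = x$pm$pm, std.error = x$pm$se,
    conf.low = x$pm$ci_lo, conf.high = x$pm$ci_hi, p.value = x$pm$p
  )
  dplyr::bind_rows(or_rows, pm_row)
}

#' Glance at a mediation fit
#'
#' @param x An `fi_mediation` object.
#' @param ... Unused.
#' @method glance fi_mediation
#' @export
glance.fi_mediation <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, n = x$n, prevalence = x$prevalence,
    interaction = x$spec$interaction,
    a = x$spec$a, a_star = x$spec$a_star,
    path_a = x$mediator_fit$beta1,
    path_b = x$outcome_fit$theta2,
    path_c = x$outcome_fit$theta1,
    max_vif = max(x$vif),
    outcome_loglik = x$outcome_fit$loglik,
    converged = x$outcome_fit$converged
  )
}

#' Bootstrap confidence intervals for the mediation estimands
#'
#' Participant-level resampling with replacement: both models are refitted
#' per resample and the natural effects recomputed at the *original*
#' exposure contrast and conditioning values, giving percentile intervals
#' that do not rest on the delta-method linearisation. Resamples where a
#' model fails (separation, non-convergence) are dropped and counted; more
#' than 10% dropped resamples aborts, since the data are then too unstable
#' for the bootstrap to be trusted.
#'
#' @inheritParams mediate_age_frailty
#' @param B Number of bootstrap resamples (at least 200).
#' @param seed Integer seed; the caller's RNG stream is left untouched.
#' @return A list with `ci` (tibble of percentile bounds for the TE, NDE,
#'   NIE odds ratios and PM), `draws` (B x 4 tibble of retained replicate
#'   estimates), and `n_dropped`.
#' @export
bootstrap_mediation <- function(data, outcome = c("composite", "death"),
                                interaction = FALSE, B = 2000, seed = 1,
                                a = NULL, a_star = NULL, c_cond = NULL,
                                conf_level = 0.95) {
  outcome <- match.arg(outcome)
  stopifnot(B >= 200)
  required <- c("age", "sex", "race", "smoking", "nihss", "fi", outcome)
  cc <- complete_cases(data, required)
  design <- encode_design(cc$data, outcome)
  n <- length(design$y)
  a_star <- a_star %||% mean(design$exposure)
  a <- a %||% (a_star + 1)
  c_cond <- c_cond %||% colMeans(design$covariates)
  spec <- mediation_spec(a, a_star, interaction, c_cond, conf_level)

  Xm <- cbind(`(Intercept)` = 1, age = design$exposure, design$covariates)
  Xo <- cbind(`(Intercept)` = 1, age = design$exposure, fi = design$mediator)
  if (interaction) {
    Xo <- cbind(Xo, `age:fi` = design$exposure * design$mediator)
  }
  Xo <- cbind(Xo, design$covariates)

  one_rep <- function(idx) {
    om <- .fit_ols(Xm[idx, , drop = FALSE], design$mediator[idx])
    oo <- .fit_logit(Xo[idx, , drop = FALSE], design$y[idx])
    med <- list(beta0 = unname(om$coef[1]), beta1 = unname(om$coef[2]),
                beta2 = om$coef[-(1:2)], sigma2 = om$sigma2, coef = om$coef)
    kth <- if (interaction) 4 else 3
    out <- list(theta1 = unname(oo$coef[2]), theta2 = unname(oo$coef[3]),
                theta3 = if (interaction) unname(oo$coef[4]) else 0,
                interaction = interaction, coef = oo$coef)
    pt <- natural_effects(med, out, spec)
    c(log_te = pt$log_te, log_nde = pt$log_nde, log_nie = pt$log_nie,
      pm = proportion_mediated(exp(pt$log_nde), exp(pt$log_nie)))
  }

  draws <- .with_seed(seed, {
    replicate(B, {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(one_rep(idx), error = function(e) rep(NA_real_, 4))
    })
  })
  draws <- t(draws)
  ok <- stats::complete.cases(draws)
  n_dropped <- sum(!ok)
  if (n_dropped > 0.1 * B) {
    stop(sprintf("%d of %d bootstrap resamples failed; data too unstable",
                 n_dropped, B), call. = FALSE)
  }
  draws <- draws[ok, , drop = FALSE]
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  qs <- apply(draws, 2, stats::quantile, probs = probs, type = 7)
  ci <- tibble::tibble(
    term = c("total_effect", "natural_direct", "natural_indirect",
             "proportion_mediated"),
    lo = c(exp(qs[1, 1:3]), qs[1, 4]),
    hi = c(exp(qs[2, 1:3]), qs[2, 4])
  )
  list(ci = ci,
       draws = tibble::as_tibble(as.data.frame(draws)),
       n_dropped = n_dropped, B = B, spec = spec)
}

#' Test the exposure-mediator interaction
#'
#' Fits the outcome model with and without the age-by-frailty product
#' term and reports: the Wald test of the interaction coefficient, the
#' likelihood-ratio test of the nested pair, and how much the natural
#' direct and indirect effect estimates move when the interaction is
#' added — the three pieces of evidence for deciding whether the simpler
#' no-interaction model suffices.
#'
#' @inheritParams mediate_age_frailty
#' @return A list with `wald` (list: estimate, se, z, p), `lr` (list:
#'   statistic, df, p), and `effect_deltas` (tibble of the change in
#'   log NDE / log NIE when the interaction is included).
#' @export
test_interaction <- function(data, outcome = c("composite", "death"),
                             a = NULL, a_star = NULL, c_cond = NULL) {
  outcome <- match.arg(outcome)
  required <- c("age", "sex", "race", "smoking", "nihss", "fi", outcome)
  cc <- complete_cases(data, required)
  design <- encode_design(cc$data, outcome)
  med <- fit_mediator_model(design)
  out0 <- fit_outcome_model(design, interaction = FALSE)
  out1 <- fit_outcome_model(design, interaction = TRUE)

  a_star <- a_star %||% mean(design$exposure)
  a <- a %||% (a_star + 1)
  c_cond <- c_cond %||% colMeans(design$covariates)
  sp0 <- mediation_spec(a, a_star, FALSE, c_cond)
  sp1 <- mediation_spec(a, a_star, TRUE, c_cond)
  pt0 <- natural_effects(med, out0, sp0)
  pt1 <- natural_effects(med, out1, sp1)

  list(
    wald = wald_test(out1, "age:fi"),
    lr = lr_test(out1, out0),
    effect_deltas = tibble::tibble(
      term = c("log_nde", "log_nie"),
      without_interaction = c(pt0$log_nde, pt0$log_nie),
      with_interaction = c(pt1$log_nde, pt1$log_nie),
      delta = c(pt1$log_nde - pt0$log_nde, pt1$log_nie - pt0$log_nie)
    )
  )
}
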
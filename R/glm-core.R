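# Model-fitting layer: linear mediator regression, logistic outcome
# regression (via stats' least-squares and IRLS machinery), and the
# supporting diagnostics (VIF, Wald, likelihood-ratio tests).

# Least squares on an explicit design matrix; sigma2 = RSS/(n-p),
# vcov = sigma2 (X'X)^-1. Errors on rank deficiency, naming the columns.
.fit_ols <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need n > p for the linear model", call. = FALSE)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < p) {
    dropped <- colnames(X)[is.na(fit$coefficients)]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  R <- qr.R(fit$qr)
  xtx_inv <- chol2inv(R)
  # undo any pivoting
  piv <- fit$qr$pivot
  xtx_inv[piv, piv] <- xtx_inv
  vcov <- sigma2 * xtx_inv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coef = fit$coefficients, sigma2 = sigma2, vcov = vcov, n = n,
       residuals = fit$residuals, fitted = fit$fitted.values)
}

# Logistic ML via stats::glm.fit (IRLS). Separation is an error, not a
# fallback: pinned fitted probabilities together with runaway coefficients
# mean the MLE does not exist.
.fit_logit <- function(X, y, max_iter = 100, tol = 1e-8) {
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; logistic model is undefined",
         call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = tol, maxit = max_iter)
  ))
  p_hat <- fit$fitted.values
  pinned <- any(p_hat < 1e-6 | p_hat > 1 - 1e-6)
  runaway <- any(abs(fit$coefficients * apply(X, 2, stats::sd)) > 15,
                 na.rm = TRUE)
  if (pinned && (runaway || !fit$converged)) {
    stop("complete or quasi-complete separation detected: fitted ",
         "probabilities pinned at 0/1 with diverging coefficients",
         call. = FALSE)
  }
  if (!fit$converged) {
    stop(sprintf("logistic fit did not converge in %d iterations", max_iter),
         call. = FALSE)
  }
  w <- fit$weights
  info <- crossprod(X * sqrt(w))
  vcov <- solve(info)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  eps <- 1e-12
  loglik <- sum(y * log(pmax(p_hat, eps)) +
                  (1 - y) * log(pmax(1 - p_hat, eps)))
  list(coef = fit$coefficients, vcov = vcov, loglik = loglik,
       converged = fit$converged, n = nrow(X), fitted = p_hat)
}

#' Fit the linear mediator regression (path a)
#'
#' Regresses the frailty index on age with adjustment for the covariates,
#' by ordinary least squares. The age coefficient is path *a* of the
#' mediation diagram; the residual variance feeds the interaction terms of
#' the natural-effect formulas.
#'
#' @param design A `coded_design` from [encode_design()].
#' @return A list of class `mediator_fit`: `beta0` (intercept), `beta1`
#'   (age coefficient, path a), `beta2` (named covariate coefficients),
#'   `sigma2` (residual variance), `vcov` (coefficient covariance), `n`,
#'   and `coef` (the full named coefficient vector).
#' @export
fit_mediator_model <- function(design) {
  stopifnot(inherits(design, "coded_design"))
  X <- cbind(`(Intercept)` = 1, age = design$exposure, design$covariates)
  fit <- .fit_ols(X, design$mediator)
  structure(
    list(beta0 = unname(fit$coef[1]), beta1 = unname(fit$coef[2]),
         beta2 = fit$coef[-(1:2)], sigma2 = fit$sigma2, vcov = fit$vcov,
         n = fit$n, coef = fit$coef, residuals = fit$residuals),
    class = "mediator_fit"
  )
}

#' Fit the logistic outcome regression (paths b and c)
#'
#' Regresses a binary 90-day outcome on age with adjustment for the
#' mediator (frailty index) and the covariates, by maximum likelihood
#' (IRLS). The age coefficient is path *c* (direct), the mediator
#' coefficient path *b*; with `interaction = TRUE` an age-by-frailty
#' product term is added.
#'
#' @param design A `coded_design`.
#' @param interaction Include the exposure-mediator product term?
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   deviance.
#' @return A list of class `outcome_fit`: `theta0`, `theta1` (age, path c),
#'   `theta2` (mediator, path b), `theta3` (interaction; 0 when disabled),
#'   `theta4` (named covariate coefficients), `vcov`, `loglik`,
#'   `converged`, `interaction`, `n`, `coef`.
#' @export
fit_outcome_model <- function(design, interaction = FALSE,
                              max_iter = 100, tol = 1e-8) {
  stopifnot(inherits(design, "coded_design"))
  X <- cbind(`(Intercept)` = 1, age = design$exposure, fi = design$mediator)
  if (interaction) X <- cbind(X, `age:fi` = design$exposure * design$mediator)
  X <- cbind(X, design$covariates)
  fit <- .fit_logit(X, design$y, max_iter = max_iter, tol = tol)
  k <- if (interaction) 4 else 3
  structure(
    list(theta0 = unname(fit$coef[1]), theta1 = unname(fit$coef[2]),
         theta2 = unname(fit$coef[3]),
         theta3 = if (interaction) unname(fit$coef[4]) else 0,
         theta4 = fit$coef[-seq_len(k)],
         vcov = fit$vcov, loglik = fit$loglik, converged = fit$converged,
         interaction = interaction, n = fit$n, coef = fit$coef,
         fitted = fit$fitted),
    class = "outcome_fit"
  )
}

#' Variance inflation factors
#'
#' VIF_j = 1/(1 - R^2_j), where R^2_j comes from regressing predictor j on
#' the remaining predictors (intercept included in each auxiliary
#' regression but excluded from the VIF list). Values above 3 are flagged
#' by the pipeline's multicollinearity screen; exactly collinear columns
#' report an infinite VIF with a warning.
#'
#' @param X Numeric design matrix whose first column is the intercept, or a
#'   `coded_design` (VIFs for the outcome-model design without
#'   interaction).
#' @return Named numeric vector of VIFs, one per non-intercept column.
#' @export
vif <- function(X) {
  if (inherits(X, "coded_design")) {
    X <- cbind(`(Intercept)` = 1, age = X$exposure, fi = X$mediator,
               X$covariates)
  }
  stopifnot(is.matrix(X), ncol(X) >= 3)
  idx <- 2:ncol(X)
  out <- vapply(idx, function(j) {
    yj <- X[, j]
    Xj <- X[, -j, drop = FALSE]
    fit <- stats::lm.fit(Xj, yj)
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)[idx]
  if (any(is.infinite(out))) {
    warning("exact collinearity: infinite VIF for ",
            paste(names(out)[is.infinite(out)], collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Wald z-test for a single coefficient
#'
#' @param fit A `mediator_fit` or `outcome_fit`.
#' @param term Coefficient name (e.g. `"age"`, `"fi"`, `"age:fi"`) or index
#'   into the coefficient vector.
#' @return A list with `estimate`, `se`, `z`, `p` (two-sided, standard
#'   normal reference).
#' @export
wald_test <- function(fit, term) {
  coefs <- fit$coef
  if (is.character(term)) {
    if (!term %in% names(coefs)) {
      stop("no coefficient named '", term, "'", call. = FALSE)
    }
    idx <- match(term, names(coefs))
  } else {
    idx <- term
  }
  est <- unname(coefs[idx])
  se <- sqrt(fit$vcov[idx, idx])
  if (se == 0) stop("zero standard error; Wald test undefined", call. = FALSE)
  z <- est / se
  list(estimate = est, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Likelihood-ratio test for nested logistic models
#'
#' @param full,reduced `outcome_fit` objects, `reduced` nested in `full`.
#' @return A list with `statistic` (twice the log-likelihood difference),
#'   `df`, and `p` (upper-tail chi-square).
#' @export
lr_test <- function(full, reduced) {
  df <- length(full$coef) - length(reduced$coef)
  if (df < 0) stop("'full' has fewer parameters than 'reduced'", call. = FALSE)
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < -1e-6) {
    stop("full-model log-likelihood below reduced model's: fitting failure",
         call. = FALSE)
  }
  stat <- max(stat, 0)
  p <- if (df == 0) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}
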
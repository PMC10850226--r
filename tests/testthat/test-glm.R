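# Fits are checked against independent oracles: the normal equations for
# least squares and a coarse-to-fine grid search on the likelihood for
# the logistic model.

make_design <- function(n, seed, prevalence = 0.3) {
  p <- sim_params(n = n, target_prevalence = prevalence, seed = seed)
  cohort <- suppressWarnings(simulate_cohort(p))
  encode_design(cohort, "composite")
}

test_that("least squares recovers exact lines and means", {
  X <- cbind(`(Intercept)` = 1, x = c(0, 1, 2))
  fit <- frailtymed:::.fit_ols(X, c(1, 3, 5))
  expect_equal(unname(fit$coef), c(1, 2))
  expect_equal(fit$sigma2, 0)

  X0 <- cbind(`(Intercept)` = rep(1, 10))
  y <- rnorm(10)
  expect_equal(unname(frailtymed:::.fit_ols(X0, y)$coef), mean(y))
})

test_that("least squares matches the normal-equation oracle", {
  set.seed(31)
  X <- cbind(1, matrix(rnorm(50 * 3), 50, 3))
  colnames(X) <- c("(Intercept)", "a", "b", "c")
  y <- rnorm(50)
  fit <- frailtymed:::.fit_ols(X, y)
  oracle <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(fit$coef), unname(drop(oracle)), tolerance = 1e-10)
  # residuals orthogonal to the design
  expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-8)
  # vcov agrees with sigma2 (X'X)^-1
  expect_equal(fit$vcov,
               fit$sigma2 * solve(crossprod(X)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("rank-deficient designs error naming the collinear column", {
  X <- cbind(`(Intercept)` = 1, a = 1:10, dup = 1:10)
  expect_error(frailtymed:::.fit_ols(X, rnorm(10)), "dup")
})

test_that("logistic intercept-only fit equals the log-odds of prevalence", {
  y <- rep(c(1, 0), c(25, 75))
  X <- cbind(`(Intercept)` = rep(1, 100))
  fit <- frailtymed:::.fit_logit(X, y)
  expect_equal(unname(fit$coef), log(0.25 / 0.75), tolerance = 1e-8)
})

test_that("logistic ML matches a coarse-to-fine grid-search oracle", {
  set.seed(77)
  n <- 500
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- frailtymed:::.fit_logit(X, y)

  loglik <- function(b0, b1) {
    p <- plogis(b0 + b1 * x)
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  centre <- c(0, 0); width <- 3
  for (step in 1:6) {
    g0 <- seq(centre[1] - width, centre[1] + width, length.out = 41)
    g1 <- seq(centre[2] - width, centre[2] + width, length.out = 41)
    ll <- outer(g0, g1, Vectorize(loglik))
    best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    centre <- c(g0[best[1]], g1[best[2]])
    width <- width / 10
  }
  expect_equal(unname(fit$coef), centre, tolerance = 1e-4)
  # score equations hold at the optimum
  expect_lt(max(abs(crossprod(X, y - fit$fitted))), 1e-6)
})

test_that("perfect separation is an explicit error", {
  x <- rep(c(0, 1), each = 20)
  X <- cbind(`(Intercept)` = 1, x = x)
  expect_error(frailtymed:::.fit_logit(X, x), "separation")
  expect_error(frailtymed:::.fit_logit(X, rep(1, 40)), "single class")
})

test_that("VIF is 1 for orthogonal designs, infinite for duplicates, and
           matches the two-predictor closed form", {
  n <- 64
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4)
  X <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2)
  expect_equal(unname(vif(X)), c(1, 1), tolerance = 1e-10)

  expect_warning(v <- vif(cbind(X, dup = x1)), "collinear")
  expect_true(is.infinite(v["dup"]))

  set.seed(13)
  a <- rnorm(200)
  b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(200)
  Xr <- cbind(`(Intercept)` = 1, a = a, b = b)
  r <- cor(a, b)
  expect_equal(unname(vif(Xr)), rep(1 / (1 - r^2), 2), tolerance = 1e-10)
})

test_that("VIF agrees with the car implementation on a fitted model", {
  skip_if_not_installed("car")
  d <- make_design(300, seed = 4)
  df <- data.frame(y = d$y, age = d$exposure, fi = d$mediator, d$covariates)
  lmfit <- lm(y ~ age + fi + sex_male + race_white + smoking_former +
                smoking_current + nihss, data = df)
  ours <- vif(cbind(`(Intercept)` = 1, age = d$exposure, fi = d$mediator,
                    d$covariates))
  expect_equal(unname(ours), unname(car::vif(lmfit)), tolerance = 1e-8)
})

test_that("Wald p-values match the normal-CDF closed form", {
  med <- fake_med_fit(0, 0.5, vcov = diag(3), beta2 = c(a = 0.1))
  w <- wald_test(med, "age")
  expect_equal(w$z, 0.5)
  expect_equal(w$p, 2 * (1 - pnorm(0.5)))
  w196 <- wald_test(fake_med_fit(0, 1.96, vcov = diag(4),
                                 beta2 = c(a = 0, b = 0)), "age")
  expect_equal(w196$p, 0.05, tolerance = 1e-3)
  expect_error(wald_test(fake_med_fit(0, 1), "age"), "zero standard error")
  expect_error(wald_test(med, "nope"), "no coefficient")
})

test_that("likelihood-ratio test has the chi-square reference", {
  d <- make_design(400, seed = 6)
  full <- fit_outcome_model(d, interaction = TRUE)
  reduced <- fit_outcome_model(d, interaction = FALSE)
  lr <- lr_test(full, reduced)
  expect_equal(lr$df, 1)
  expect_gte(lr$statistic, 0)
  expect_equal(lr$p, pchisq(lr$statistic, 1, lower.tail = FALSE))

  same <- lr_test(reduced, reduced)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(lr_test(reduced, full), "fewer parameters")
})

test_that("null LR statistics follow chi-square(1) across replicates", {
  # mediator carries no effect beyond the null model here: simulate a
  # null predictor and test its LR contribution
  set.seed(99)
  stats <- replicate(300, {
    n <- 150
    y <- rbinom(n, 1, 0.3)
    z <- rnorm(n)
    X0 <- cbind(`(Intercept)` = rep(1, n))
    X1 <- cbind(X0, z = z)
    f0 <- frailtymed:::.fit_logit(X0, y)
    f1 <- frailtymed:::.fit_logit(X1, y)
    2 * (f1$loglik - f0$loglik)
  })
  ks <- suppressWarnings(ks.test(stats, pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
})
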
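test_that("ols_fit interpolates noiseless data and matches lm on noisy data", {
  set.seed(1)
  X <- cbind(`(Intercept)` = 1, a = rnorm(50), b = rnorm(50))
  beta <- c(2, -1, 0.5)
  y0 <- drop(X %*% beta)
  fit0 <- ols_fit(y0, X)
  expect_equal(unname(fit0$coefficients), beta, tolerance = 1e-10)
  expect_equal(max(abs(fit0$residuals)), 0, tolerance = 1e-10)
  # independent solver: lm coefficients on random data
  y <- y0 + rnorm(50)
  fit <- ols_fit(y, X)
  ref <- stats::lm(y ~ a + b, data = data.frame(y = y, a = X[, 2],
                                                b = X[, 3]))
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-10)
})

test_that("HC1 robust errors approach classical errors when homoskedastic", {
  set.seed(2)
  n <- 4000
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 2)) + rnorm(n)
  fit <- ols_fit(y, X)
  ref <- stats::lm(y ~ X[, 2])
  cl <- sqrt(diag(stats::vcov(ref)))
  expect_lt(max(abs(fit$robust_se - cl) / cl), 0.1)
})

test_that("rank-deficient designs are rejected with the offending column", {
  X <- cbind(`(Intercept)` = 1, a = 1:10, twice_a = 2 * (1:10))
  expect_error(ols_fit(rnorm(10), X), "twice_a")
})

test_that("2SLS equals OLS when instrumenting with the regressor itself", {
  set.seed(3)
  d <- toy_iv_data(300, seed = 3)
  X2 <- cbind(`(Intercept)` = rep(1, nrow(d)))
  iv <- tsls_fit(d$y, cbind(x = d$x), X2, cbind(z = d$x))
  ols <- ols_fit(d$y, cbind(x = d$x, X2))
  expect_equal(iv$coefficients[["x"]], ols$coefficients[["x"]],
               tolerance = 1e-10)
})

test_that("exactly identified 2SLS equals the Wald ratio closed form", {
  d <- toy_iv_data(20, seed = 4)
  X2 <- cbind(`(Intercept)` = rep(1, 20))
  iv <- tsls_fit(d$y, cbind(x = d$x), X2, cbind(z = d$z))
  expect_equal(iv$coefficients[["x"]], oracle_wald_ratio(d$y, d$x, d$z),
               tolerance = 1e-10)
  # and the two-step lm route gives the same coefficients
  xhat <- stats::fitted(stats::lm(x ~ z, data = d))
  two_step <- stats::coef(stats::lm(d$y ~ xhat))
  expect_equal(unname(iv$coefficients[c("x", "(Intercept)")]),
               unname(two_step[c("xhat", "(Intercept)")]),
               tolerance = 1e-8)
})

test_that("2SLS is invariant to nonsingular reparameterization of Z", {
  set.seed(5)
  n <- 400
  u <- rnorm(n); z1 <- rnorm(n); z2 <- rnorm(n)
  x <- 0.5 * z1 + 0.3 * z2 + 0.8 * u + rnorm(n)
  y <- 0.3 * x + u + rnorm(n)
  X2 <- cbind(`(Intercept)` = rep(1, n))
  Z <- cbind(z1, z2)
  A <- matrix(c(2, 1, -1, 3), 2, 2)
  f1 <- tsls_fit(y, cbind(x = x), X2, Z)
  f2 <- tsls_fit(y, cbind(x = x), X2, Z %*% A)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
})

test_that("2SLS recovers the structural effect where OLS is inconsistent", {
  # plim of OLS from the DGP covariances: beta + gamma*delta/var(x)
  est <- t(vapply(1:60, function(s) {
    d <- toy_iv_data(2000, seed = s)
    X2 <- cbind(`(Intercept)` = rep(1, 2000))
    c(iv = tsls_fit(d$y, cbind(x = d$x), X2,
                    cbind(z = d$z))$coefficients[["x"]],
      ols = ols_fit(d$y, cbind(x = d$x, X2))$coefficients[["x"]])
  }, numeric(2)))
  plim_ols <- 0.3 + 1 * 0.8 / (0.6^2 + 0.8^2 + 1)
  expect_lt(abs(mean(est[, "iv"]) - 0.3), 0.02)
  expect_lt(abs(mean(est[, "ols"]) - plim_ols), 0.02)
  expect_gt(mean(est[, "ols"]), 0.4)
})

test_that("first-stage F equals the squared robust t for one instrument", {
  d <- toy_iv_data(500, seed = 6)
  X2 <- cbind(`(Intercept)` = rep(1, 500))
  fs <- first_stage(cbind(x = d$x), X2, cbind(z = d$z))
  fit <- ols_fit(d$x, cbind(X2, z = d$z))
  expect_equal(fs$F[["x"]], (fit$coefficients[["z"]] /
                             fit$robust_se[["z"]])^2,
               tolerance = 1e-10)
})

test_that("irrelevant instruments give low F, relevant ones high F", {
  set.seed(7)
  n <- 2000
  Fs <- vapply(1:30, function(s) {
    set.seed(s)
    x <- rnorm(n); z <- rnorm(n)   # orthogonal
    first_stage(cbind(x = x), cbind(`(Intercept)` = rep(1, n)),
                cbind(z = z))$F[["x"]]
  }, numeric(1))
  expect_gt(mean(Fs < 10), 0.9)
  # strong instruments: partial R2 ~ 0.2 at n = 2000 -> F > 10 in >= 95%
  Fs2 <- vapply(1:40, function(s) {
    set.seed(100 + s)
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)        # R2 = 0.2
    first_stage(cbind(x = x), cbind(`(Intercept)` = rep(1, n)),
                cbind(z = z))$F[["x"]]
  }, numeric(1))
  expect_gte(mean(Fs2 > 10), 0.95)
})

test_that("under-identified or collinear instrument sets are rejected", {
  d <- toy_iv_data(100, seed = 8)
  X2 <- cbind(`(Intercept)` = rep(1, 100), w = rnorm(100))
  expect_error(tsls_fit(d$y, cbind(x = d$x, x2 = d$u), X2,
                        cbind(z = d$z)),
               "under-identified")
  expect_error(tsls_fit(d$y, cbind(x = d$x), X2,
                        cbind(z = X2[, "w"])), "singular|collinear")
})

test_that("Wu-Hausman control-function test is calibrated and powerful", {
  # no confounding: rejection near the nominal 5% level
  p_null <- vapply(1:200, function(s) {
    d <- toy_iv_data(1000, gamma = 0, delta = 0, seed = 1000 + s)
    wu_hausman(d$y, cbind(x = d$x),
               cbind(`(Intercept)` = rep(1, 1000)), cbind(z = d$z))$p
  }, numeric(1))
  expect_gte(mean(p_null < 0.05), 0.02)
  expect_lte(mean(p_null < 0.05), 0.09)
  # strong confounding: high power
  p_alt <- vapply(1:60, function(s) {
    d <- toy_iv_data(1000, seed = 2000 + s)
    wu_hausman(d$y, cbind(x = d$x),
               cbind(`(Intercept)` = rep(1, 1000)), cbind(z = d$z))$p
  }, numeric(1))
  expect_gte(mean(p_alt < 0.05), 0.8)
})

test_that("contrast-form and control-function Wu-Hausman agree in decision", {
  agree <- vapply(1:60, function(s) {
    d <- toy_iv_data(800, gamma = if (s %% 2) 1 else 0,
                     delta = if (s %% 2) 0.8 else 0, seed = 3000 + s)
    X2 <- cbind(`(Intercept)` = rep(1, 800))
    a <- wu_hausman(d$y, cbind(x = d$x), X2, cbind(z = d$z))$p < 0.05
    b <- wu_hausman(d$y, cbind(x = d$x), X2, cbind(z = d$z),
                    method = "contrast")$p < 0.05
    a == b
  }, logical(1))
  expect_gte(mean(agree), 0.9)
})

test_that("wald_equality: self-comparison is null, planted gaps are found", {
  d <- toy_iv_data(800, seed = 9)
  X2 <- cbind(`(Intercept)` = rep(1, 800))
  fit <- tsls_fit(d$y, cbind(x = d$x), X2, cbind(z = d$z))
  refit <- function(idx) tsls_fit(d$y[idx], cbind(x = d$x[idx]),
                                  X2[idx, , drop = FALSE],
                                  cbind(z = d$z[idx]))$coefficients
  self <- wald_equality(fit, fit, "x", refit_a = refit, refit_b = refit,
                        n_index = 800, n_boot = 120, seed = 1)
  expect_equal(self$stat, 0)
  expect_equal(self$p, 1)
  expect_error(wald_equality(fit, fit, "nope"), "not present")
  # analytic variant with two clearly different estimands rejects
  d2 <- d; d2$y <- d$y + 2 * d$x
  fit2 <- tsls_fit(d2$y, cbind(x = d2$x), X2, cbind(z = d2$z))
  an <- wald_equality(fit, fit2, "x", method = "analytic")
  expect_lt(an$p, 0.05)
})

test_that("OLS and 2SLS converge with no confounding; confounding can
          attenuate OLS toward zero", {
  # generator-level check: confounder off
  diffs <- vapply(1:25, function(s) {
    cfg <- sim_config(n_users = 1200, confounder_sd = 0, seed = 5000 + s)
    g <- generate_follow_graph(cfg)
    tr <- generate_traits(g, cfg)
    out <- generate_linear_outcome(tr, cfg)
    inst <- build_instruments(g, stats::setNames(tr$emotion, tr$user_id))
    idx <- match(inst$user_id, tr$user_id)
    ok <- !is.na(inst$value)
    X2 <- cbind(`(Intercept)` = rep(1, sum(ok)))
    iv <- tsls_fit(out$propensity[idx][ok],
                   cbind(emotion = tr$emotion[idx][ok]), X2,
                   cbind(z = inst$value[ok]))$coefficients[["emotion"]]
    ols <- ols_fit(out$propensity[idx][ok],
                   cbind(emotion = tr$emotion[idx][ok],
                         X2))$coefficients[["emotion"]]
    iv - ols
  }, numeric(1))
  expect_lt(mean(abs(diffs)), 0.02)
  # attenuating confounding (loadings of opposite sign): |IV| > |OLS|
  bigger <- vapply(1:15, function(s) {
    cfg <- sim_config(n_users = 1500, gamma_linear = -1, seed = 6000 + s)
    g <- generate_follow_graph(cfg)
    tr <- generate_traits(g, cfg)
    out <- generate_linear_outcome(tr, cfg)
    inst <- build_instruments(g, stats::setNames(tr$emotion, tr$user_id))
    idx <- match(inst$user_id, tr$user_id)
    ok <- !is.na(inst$value)
    X2 <- cbind(`(Intercept)` = rep(1, sum(ok)))
    iv <- tsls_fit(out$propensity[idx][ok],
                   cbind(emotion = tr$emotion[idx][ok]), X2,
                   cbind(z = inst$value[ok]))$coefficients[["emotion"]]
    ols <- ols_fit(out$propensity[idx][ok],
                   cbind(emotion = tr$emotion[idx][ok],
                         X2))$coefficients[["emotion"]]
    abs(iv) > abs(ols)
  }, logical(1))
  expect_gte(mean(bigger), 0.9)
})
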
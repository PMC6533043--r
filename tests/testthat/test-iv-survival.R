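# small confounded additive-hazard DGP used across several blocks:
# h = b0 + he * emotion + hu * confounder, emotion = 0.6 * z + 0.8 * u + v,
# censored at tau days
hazard_dgp <- function(n, he = 0.02, hu = 0.04, b0 = 0.1, tau = 30,
                       seed = 1) {
  set.seed(seed)
  u <- stats::rnorm(n, 0, 0.5)
  z <- stats::rnorm(n, 0, 0.7)
  x <- 0.6 * z + 0.8 * u + stats::rnorm(n, 0, 0.8)
  h <- pmax(0, b0 + he * x + hu * u)
  t_true <- ifelse(h > 0, stats::rexp(n) / h, Inf)
  data.frame(time = pmin(t_true, tau), event = as.integer(t_true < tau),
             x = x, z = z, u = u)
}

test_that("kaplan_meier reproduces the hand product-limit fixture", {
  # times {1, 2+, 3, 4}: S(1) = 3/4, S(3) = 3/8
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 0, 1, 1))
  expect_equal(km$surv[km$time == 1], 3 / 4, tolerance = 1e-12)
  expect_equal(km$surv[km$time == 3], 3 / 8, tolerance = 1e-12)
  # matches the hand oracle on random censored data, in any input order
  set.seed(21)
  tm <- round(stats::rexp(80, 0.2), 2) + 0.01
  ev <- stats::rbinom(80, 1, 0.7)
  km1 <- kaplan_meier(tm, ev)
  o <- oracle_km(tm, ev)
  expect_equal(km1$surv[match(o$time, km1$time)], o$surv,
               tolerance = 1e-12)
  shuffle <- sample(80)
  km2 <- kaplan_meier(tm[shuffle], ev[shuffle])
  expect_identical(km1$surv, km2$surv)
})

test_that("kaplan_meier: no censoring reduces to the empirical survivor
          function; all-censored flags the median", {
  tm <- c(5, 1, 3, 2, 4)
  km <- kaplan_meier(tm, rep(1, 5))
  ecdf_surv <- 1 - stats::ecdf(tm)(km$time)
  expect_equal(km$surv, ecdf_surv, tolerance = 1e-12)
  expect_warning(km0 <- kaplan_meier(tm, rep(0, 5)), "no events")
  expect_false(km0$median_defined)
})

test_that("exponential sample: KM median within 5% of ln(2)/rate", {
  set.seed(22)
  n <- 10000
  t_true <- stats::rexp(n, 0.1)
  cens <- stats::rexp(n, 0.025)            # ~20% independent censoring
  km <- kaplan_meier(pmin(t_true, cens), as.integer(t_true <= cens))
  expect_lt(abs(km$median - log(2) / 0.1) / (log(2) / 0.1), 0.05)
})

test_that("aalen_fit equals the Nelson-Aalen difference for one binary
          covariate", {
  set.seed(23)
  n <- 300
  grp <- stats::rbinom(n, 1, 0.5)
  h <- 0.05 + 0.04 * grp
  t_true <- stats::rexp(n) / h
  tau <- 25
  time <- pmin(t_true, tau); event <- as.integer(t_true < tau)
  fit <- aalen_fit(time, event, cbind(grp = grp))
  na1 <- oracle_nelson_aalen(time[grp == 1], event[grp == 1])
  na0 <- oracle_nelson_aalen(time[grp == 0], event[grp == 0])
  step_at <- function(na, t) vapply(t, function(tt) {
    i <- which(na$time <= tt + 1e-12)
    if (length(i) == 0) 0 else na$H[max(i)]
  }, numeric(1))
  want <- step_at(na1, fit$times) - step_at(na0, fit$times)
  expect_equal(unname(fit$B[, "grp"]), want, tolerance = 1e-10)
  # and the intercept is the group-0 Nelson-Aalen
  expect_equal(unname(fit$B[, "(Intercept)"]), step_at(na0, fit$times),
               tolerance = 1e-10)
})

test_that("aalen_fit agrees with the pure-R least-squares oracle and with
          survival::aareg increments", {
  d <- hazard_dgp(150, seed = 24)
  X <- cbind(x = d$x, u = d$u)
  fit <- aalen_fit(d$time, d$event, X)
  o <- oracle_aalen(d$time, d$event, X)
  k <- length(fit$times)
  expect_equal(fit$times, o$times[seq_len(k)])
  expect_equal(unname(fit$B),
               unname(o$B[seq_len(k), c(1, 2, 3)]), tolerance = 1e-8)
  # independent library cross-check on the increments it reports
  ar <- survival::aareg(survival::Surv(time, event) ~ x + u, data = d,
                        nmin = 1)
  k2 <- min(k, nrow(ar$coefficient))
  expect_equal(unname(fit$dB[seq_len(k2), c("x", "u")]),
               unname(ar$coefficient[seq_len(k2), c("x", "u")]),
               tolerance = 1e-6)
})

test_that("aalen cumulative coefficients are translation-equivariant", {
  d <- hazard_dgp(200, seed = 25)
  f1 <- aalen_fit(d$time, d$event, cbind(x = d$x))
  f2 <- aalen_fit(d$time, d$event, cbind(x = d$x + 5))
  expect_equal(f1$B[, "x"], f2$B[, "x"], tolerance = 1e-8)
  expect_equal(f2$B[, "(Intercept)"],
               f1$B[, "(Intercept)"] - 5 * f1$B[, "x"], tolerance = 1e-8)
})

test_that("mean_coefficient returns the slope of a linear B(t) and recovers
          constant hazard effects", {
  fit <- structure(list(times = 1:10,
                        B = cbind(x = 0.02 * (1:10), y = -1 * (1:10))),
                   class = "aalen_fit")
  mc <- mean_coefficient(fit)
  expect_equal(unname(mc), c(0.02, -1), tolerance = 1e-12)
  expect_equal(unname(mean_coefficient(fit, method = "terminal")),
               c(0.02, -1), tolerance = 1e-12)
  # h = 0.01 + 0.02 x: fitted slope within 15% at large n
  set.seed(26)
  n <- 2000
  x <- stats::runif(n)
  h <- 0.01 + 0.02 * x
  t_true <- stats::rexp(n) / h
  tau <- 60
  f <- aalen_fit(pmin(t_true, tau), as.integer(t_true < tau),
                 cbind(x = x))
  expect_lt(abs(mean_coefficient(f)[["x"]] - 0.02) / 0.02, 0.15)
})

test_that("degenerate aalen inputs error clearly", {
  expect_error(aalen_fit(c(1, 2), c(0, 0), cbind(x = c(1, 2))),
               "no events")
  expect_error(mean_coefficient(structure(list(times = 1,
                                               B = cbind(x = 0.1)),
                                          class = "aalen_fit")),
               "fewer than 2")
})

test_that("aalen_iv_fit with zero first-stage residuals equals aalen_fit", {
  d <- hazard_dgp(150, seed = 27)
  # x exactly linear in z: residuals are numerically zero
  d$x <- 2 * d$z
  iv <- aalen_iv_fit(d$time, d$event, cbind(x = d$x),
                     matrix(nrow = 150, ncol = 0), cbind(z = d$z))
  plain <- aalen_fit(d$time, d$event, cbind(x = d$x))
  expect_equal(iv$B[, "x"], plain$B[, "x"], tolerance = 1e-6)
})

test_that("control-function IV removes confounding bias the naive fit keeps", {
  est <- t(vapply(1:40, function(s) {
    d <- hazard_dgp(1000, seed = 400 + s)
    naive <- mean_coefficient(
      aalen_fit(d$time, d$event, cbind(x = d$x)))[["x"]]
    iv <- mean_coefficient(
      aalen_iv_fit(d$time, d$event, cbind(x = d$x),
                   matrix(nrow = 1000, ncol = 0),
                   cbind(z = d$z)))[["x"]]
    c(naive = naive, iv = iv)
  }, numeric(2)))
  expect_lt(abs(mean(est[, "iv"]) - 0.02) / 0.02, 0.25)
  expect_gt(abs(mean(est[, "naive"]) - 0.02) / 0.02, 0.25)
})

test_that("no confounding: IV and standard Aalen means agree", {
  est <- t(vapply(1:25, function(s) {
    d <- hazard_dgp(800, hu = 0, seed = 500 + s)
    c(std = mean_coefficient(
        aalen_fit(d$time, d$event, cbind(x = d$x)))[["x"]],
      iv = mean_coefficient(
        aalen_iv_fit(d$time, d$event, cbind(x = d$x),
                     matrix(nrow = 800, ncol = 0),
                     cbind(z = d$z)))[["x"]])
  }, numeric(2)))
  d_mean <- mean(est[, "iv"] - est[, "std"])
  expect_lt(abs(d_mean), 2 * stats::sd(est[, "iv"] - est[, "std"]) /
                         sqrt(nrow(est)) + 0.002)
})

test_that("bootstrap_ci is deterministic under a seed and near-degenerate on
          a deterministic statistic", {
  d <- hazard_dgp(300, seed = 28)
  fit_fun <- function(idx) mean_coefficient(
    aalen_fit(d$time[idx], d$event[idx], cbind(x = d$x[idx])))
  ci1 <- bootstrap_ci(fit_fun, n = 300, n_boot = 100, seed = 5)
  ci2 <- bootstrap_ci(fit_fun, n = 300, n_boot = 100, seed = 5)
  expect_identical(ci1$lower, ci2$lower)
  expect_identical(ci1$upper, ci2$upper)
  expect_true(all(ci1$lower <= ci1$estimate + 1e-12))
  expect_true(all(ci1$upper >= ci1$estimate - 1e-12))
  # a statistic that ignores the resample has zero-width intervals
  const_fun <- function(idx) c(k = 1.23)
  cc <- bootstrap_ci(const_fun, n = 300, n_boot = 100, seed = 6)
  expect_equal(unname(cc$lower), 1.23)
  expect_equal(unname(cc$upper), 1.23)
})

test_that("IV survival fit reports a strong joint instrument F on
          strong-instrument panels", {
  cfg <- sim_config(n_users = 1500, seed = 29)
  g <- generate_follow_graph(cfg)
  tr <- generate_traits(g, cfg)
  tt <- suppressWarnings(sim_dropout_times(tr, cfg))
  time <- pmin(tt - tr$created_at, 400)
  event <- as.integer(tt - tr$created_at < 400)
  inst_e <- build_instruments(g, stats::setNames(tr$emotion, tr$user_id))
  inst_c <- build_instruments(g, stats::setNames(tr$centrality,
                                                 tr$user_id))
  idx <- match(inst_e$user_id, tr$user_id)
  ok <- !is.na(inst_e$value) & !is.na(inst_c$value)
  iv <- aalen_iv_fit(time[idx][ok], event[idx][ok],
                     cbind(emotion = tr$emotion[idx][ok],
                           centrality = tr$centrality[idx][ok]),
                     matrix(nrow = sum(ok), ncol = 0),
                     cbind(z_e = inst_e$value[ok],
                           z_c = inst_c$value[ok]))
  expect_gt(iv$first_stage_F[["emotion"]], 10)
  expect_gt(iv$first_stage_F[["centrality"]], 10)
})
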
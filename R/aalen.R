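## Survival estimation: Kaplan-Meier, Aalen's additive hazards model with
## time-varying cumulative coefficients, the control-function IV extension,
## mean-coefficient summaries and nonparametric (case) bootstrap intervals.

#' Kaplan-Meier survival curve and median
#'
#' Product-limit estimator S(t) = prod_{t_i <= t} (1 - d_i / n_i) (computed
#' through `survival::survfit`), with the median defined as the smallest
#' event time with S(t) <= 0.5; if the curve never reaches 0.5 the median is
#' `NA` and flagged.
#'
#' @param time numeric durations at risk.
#' @param event 0/1 event indicators (1 = dropout observed).
#' @return object of class `km_fit`: list `time`, `surv`, `n_risk`,
#'   `n_event`, `median`, `median_defined`.
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (sum(event) < 1) warning("kaplan_meier: no events; median undefined")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- sf$time[sf$surv <= 0.5 + 1e-12]
  med <- if (length(med) > 0) min(med) else NA_real_
  structure(list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                 n_event = sf$n.event, median = med,
                 median_defined = !is.na(med)),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier curve over", length(x$time), "times; median =",
      if (x$median_defined) format(x$median) else "undefined", "\n")
  invisible(x)
}

#' Aalen's additive hazards model
#'
#' Least-squares estimation of the cumulative regression functions B_k(t):
#' at each distinct event time the increment is
#' dB = (X'X)^{-1} X' dN over the at-risk set (ties processed together),
#' and B_k(t) is the running sum, starting at B(0) = 0.  Estimation stops at
#' the first event time whose at-risk design is singular or has condition
#' number above `cond_cap` (standard tail truncation); the reliable window
#' is everything before that point.  Covariates are constant per subject;
#' all effects are time-varying by construction.
#'
#' @param time durations at risk.
#' @param event 0/1 event indicators.
#' @param X covariate matrix (an intercept column is added when absent).
#' @param cond_cap condition-number cap for the at-risk design (default
#'   1e8).
#' @return object of class `aalen_fit`: `times` (event-time grid), `B`
#'   (cumulative coefficient matrix, one column per covariate), `dB`,
#'   `n_at_risk`, `n_events`, `truncated`, `n`, `covariates`.
#' @export
aalen_fit <- function(time, event, X, cond_cap = 1e8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!any(apply(X, 2, function(c) all(c == c[1]))))
    X <- add_intercept(X)
  stopifnot(length(time) == length(event), nrow(X) == length(time))
  if (sum(event) == 0)
    stop("aalen_fit: no events to estimate from", call. = FALSE)
  # column equilibration: the condition cap applies to the RMS-scaled
  # design, so covariate units do not drive the truncation point
  scale_j <- sqrt(colMeans(X^2))
  scale_j[scale_j == 0] <- 1
  res <- aalen_increments_cpp(as.numeric(time), as.integer(event),
                              sweep(X, 2, scale_j, "/"), cond_cap)
  res$dB <- sweep(res$dB, 2, scale_j, "/")
  if (res$used == 0)
    stop("aalen_fit: estimation impossible, singular at-risk design at the ",
         "first event time", call. = FALSE)
  dB <- res$dB
  colnames(dB) <- colnames(X)
  B <- apply(dB, 2, cumsum)
  if (!is.matrix(B))
    B <- matrix(B, nrow = 1, dimnames = list(NULL, colnames(dB)))
  structure(list(times = res$times, B = B, dB = dB,
                 n_at_risk = res$n_at_risk, n_events = res$n_events,
                 truncated = res$truncated, n = length(time),
                 covariates = colnames(X), mode = "standard"),
            class = "aalen_fit")
}

#' @export
print.aalen_fit <- function(x, ...) {
  cat("Aalen additive hazards fit (", x$mode, "), n = ", x$n, ", ",
      length(x$times), " event times", if (x$truncated) " (tail truncated)",
      "\n", sep = "")
  print(round(mean_coefficient(x), 6))
  invisible(x)
}

#' Control-function IV estimation in the additive hazards model
#'
#' Stage 1 regresses each endogenous covariate on the excluded instruments
#' plus the exogenous covariates (reusing the linear first-stage code path,
#' which also reports the robust joint F of the instruments).  Stage 2 runs
#' [aalen_fit()] on the endogenous covariates, the exogenous covariates and
#' the stage-1 residuals as additional time-varying-effect covariates; the
#' endogenous covariates' coefficients are the causal estimates.
#'
#' @param time,event outcome as in [aalen_fit()].
#' @param X1 endogenous covariate matrix (e.g. emotion and centrality).
#' @param X2 exogenous covariate matrix (an intercept is added if absent).
#' @param Z excluded instrument matrix (>= ncol(X1) columns).
#' @param cond_cap as in [aalen_fit()].
#' @return an `aalen_fit` (mode `"iv"`) with extra elements
#'   `first_stage_F` and `first_stage`.
#' @export
aalen_iv_fit <- function(time, event, X1, X2, Z, cond_cap = 1e8) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2); Z <- as.matrix(Z)
  if (is.null(colnames(X1))) colnames(X1) <- paste0("endo", seq_len(ncol(X1)))
  if (ncol(Z) < ncol(X1))
    stop("under-identified: fewer instruments than endogenous covariates",
         call. = FALSE)
  X2 <- add_intercept(X2)
  fs <- first_stage(X1, X2, Z)
  Vhat <- fs$residuals
  colnames(Vhat) <- paste0("vhat_", colnames(X1))
  # residuals that are numerically zero (perfect first stage) carry no
  # information and would only make the design singular
  keep <- sqrt(colMeans(Vhat^2)) > 1e-10 * pmax(1, sqrt(colMeans(X1^2)))
  fit <- aalen_fit(time, event,
                   cbind(X1, X2, Vhat[, keep, drop = FALSE]),
                   cond_cap = cond_cap)
  fit$mode <- "iv"
  fit$first_stage_F <- fs$F
  fit$first_stage <- fs
  fit
}

#' Mean (time-averaged) coefficients of an Aalen fit
#'
#' Per covariate, the least-squares slope of the cumulative coefficient
#' B_k(t) against t over the reliable estimation window -- the constant
#' hazard effect whose cumulative line best matches the fitted step
#' function.  The terminal summary B_k(tau) / tau is available as an
#' alternative.
#'
#' @param fit an `aalen_fit`.
#' @param method `"slope"` (default) or `"terminal"`.
#' @return named numeric vector, per-day scale.
#' @export
mean_coefficient <- function(fit, method = c("slope", "terminal")) {
  method <- match.arg(method)
  t <- fit$times
  if (length(t) < 2)
    stop("mean_coefficient: fewer than 2 event times in the window",
         call. = FALSE)
  if (method == "terminal") return(fit$B[nrow(fit$B), ] / t[length(t)])
  apply(fit$B, 2, function(b) stats::cov(t, b) / stats::var(t))
}

#' Case-bootstrap percentile confidence intervals
#'
#' Resamples subjects with replacement, refits via `fit_fun` (which must
#' re-run any first stage inside, so IV uncertainty is propagated), and
#' returns percentile intervals for the named statistics.  Replicates whose
#' refit fails (e.g. singular at-risk design) are dropped and counted; a
#' warning is emitted when more than 10% are dropped.
#'
#' @param fit_fun function `idx -> named numeric vector` computing the
#'   statistics on the rows `idx` (e.g. mean coefficients of a refitted
#'   model).
#' @param n number of subjects to resample over.
#' @param n_boot bootstrap replicates (>= 100).
#' @param seed integer seed (identical seeds give identical intervals).
#' @param conf confidence level (default 0.95).
#' @return list `estimate` (fit on the full sample), `lower`, `upper`
#'   (named vectors), `n_boot`, `n_dropped`, `replicates` (matrix).
#' @export
bootstrap_ci <- function(fit_fun, n, n_boot = 1000, seed = 1L,
                         conf = 0.95) {
  stopifnot(n_boot >= 100)
  est <- fit_fun(seq_len(n))
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, length(est),
                 dimnames = list(NULL, names(est)))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    r <- tryCatch(fit_fun(idx), error = function(e) NULL)
    if (!is.null(r)) reps[b, ] <- r[names(est)]
  }
  ok <- stats::complete.cases(reps)
  n_dropped <- sum(!ok)
  if (n_dropped > 0.1 * n_boot)
    warning("bootstrap_ci: ", n_dropped, " of ", n_boot,
            " replicates dropped")
  a <- (1 - conf) / 2
  lower <- apply(reps[ok, , drop = FALSE], 2, stats::quantile, probs = a)
  upper <- apply(reps[ok, , drop = FALSE], 2, stats::quantile,
                 probs = 1 - a)
  list(estimate = est, lower = lower, upper = upper, n_boot = n_boot,
       n_dropped = n_dropped, replicates = reps[ok, , drop = FALSE])
}
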
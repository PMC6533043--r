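## Linear-probability estimation: OLS and two-stage least squares with
## heteroscedasticity-consistent (HC1) inference, first-stage relevance F,
## the regression-based Wu-Hausman endogeneity test, and a cross-
## specification Wald equality test.
##
## Matrix interface throughout: y is the outcome, X1 the endogenous
## regressor(s), X2 the exogenous covariates (intercept included by the
## caller or via add_intercept()), Z the excluded instruments.  The 2SLS
## covariance uses second-stage residuals computed from the ORIGINAL
## endogenous regressors (proper IV variance, not the naive two-step one).

add_intercept <- function(X, name = "(Intercept)") {
  X <- as.matrix(X)
  if (name %in% colnames(X)) return(X)
  out <- cbind(1, X)
  colnames(out)[1] <- name
  out
}

check_full_rank <- function(X, context) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("singular design in ", context, ": collinear column(s) ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  qr_x
}

# HC1 sandwich from a design, residuals and bread (X'X)^-1
hc1_vcov <- function(X, resid, bread) {
  n <- nrow(X); k <- ncol(X)
  meat <- crossprod(X * resid)
  n / (n - k) * (bread %*% meat %*% bread)
}

iv_result <- function(coef, vcov, n, estimator, ...) {
  se <- sqrt(diag(vcov))
  z <- coef / se
  out <- list(coefficients = coef, robust_se = se, z = z,
              p_values = 2 * stats::pnorm(-abs(z)), vcov = vcov,
              n_obs = n, estimator = estimator, ...)
  class(out) <- "iv_fit"
  out
}

#' @export
print.iv_fit <- function(x, digits = 4, ...) {
  cat(toupper(x$estimator), "fit, n =", x$n_obs, "\n")
  tab <- cbind(Beta = x$coefficients, `Robust SE` = x$robust_se,
               `P value` = x$p_values)
  print(round(tab, digits))
  if (!is.null(x$first_stage_F))
    cat("First-stage F (excluded instruments):",
        round(x$first_stage_F, 2), "\n")
  invisible(x)
}

#' Ordinary least squares with HC1 robust inference
#'
#' @param y numeric outcome vector.
#' @param X design matrix including any intercept; must be full rank (a
#'   rank-deficient design raises an error naming the collinear columns).
#' @return an `iv_fit` object: coefficients, HC1 robust standard errors,
#'   two-sided normal-approximation p-values, vcov, residuals, fitted.
#' @export
ols_fit <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(length(y) == nrow(X), nrow(X) > ncol(X))
  qr_x <- check_full_rank(X, "ols_fit")
  coef <- stats::setNames(qr.coef(qr_x, y), colnames(X))
  fitted <- drop(X %*% coef)
  resid <- y - fitted
  bread <- chol2inv(qr.R(qr_x))
  vc <- hc1_vcov(X, resid, bread)
  dimnames(vc) <- list(colnames(X), colnames(X))
  iv_result(coef, vc, length(y), "ols", residuals = resid, fitted = fitted)
}

#' First-stage regressions for IV estimators
#'
#' Regresses each endogenous column on the exogenous covariates plus the
#' excluded instruments and computes the robust (HC1) Wald F for the joint
#' significance of the excluded instruments -- the relevance diagnostic.
#' For a single excluded instrument the F equals the squared robust
#' t-statistic.
#'
#' @param X1 matrix of endogenous regressors (one column per variable).
#' @param X2 exogenous covariate matrix (including the intercept).
#' @param Z excluded instrument matrix.
#' @return list with `fitted`, `residuals` (matrices aligned with `X1`),
#'   `F` (named per endogenous variable), `fits` (per-variable `iv_fit`s).
#' @export
first_stage <- function(X1, X2, Z) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2); Z <- as.matrix(Z)
  if (is.null(colnames(X1))) colnames(X1) <- paste0("endo", seq_len(ncol(X1)))
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  W <- cbind(X2, Z)
  fitted <- X1 * NA; resid <- X1 * NA
  Fs <- stats::setNames(numeric(ncol(X1)), colnames(X1))
  fits <- list()
  zi <- ncol(X2) + seq_len(ncol(Z))
  for (j in seq_len(ncol(X1))) {
    fit <- ols_fit(X1[, j], W)
    fitted[, j] <- fit$fitted
    resid[, j] <- fit$residuals
    b <- fit$coefficients[zi]
    V <- fit$vcov[zi, zi, drop = FALSE]
    # a perfectly-fitting first stage (zero residuals) has V = 0: F -> Inf
    Fs[j] <- tryCatch(drop(t(b) %*% solve(V, b)) / length(zi),
                      error = function(e) Inf)
    fits[[colnames(X1)[j]]] <- fit
  }
  list(fitted = fitted, residuals = resid, F = Fs, fits = fits,
       df1 = ncol(Z), df2 = nrow(W) - ncol(W))
}

#' Two-stage least squares with HC1 robust inference
#'
#' First stage: each endogenous regressor on instruments + exogenous
#' covariates.  Second stage: outcome on fitted endogenous values +
#' exogenous covariates.  The covariance sandwich uses residuals recomputed
#' with the original endogenous regressors.  2SLS needs at least as many
#' excluded instruments as endogenous regressors (order condition) and
#' instruments not collinear with the exogenous covariates.
#'
#' @param y outcome vector.
#' @param X1 endogenous regressor matrix.
#' @param X2 exogenous covariate matrix (with intercept).
#' @param Z excluded instrument matrix.
#' @return an `iv_fit` with additionally `first_stage_F` (named vector) and
#'   `first_stage` (the [first_stage()] object).
#' @export
tsls_fit <- function(y, X1, X2, Z) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2); Z <- as.matrix(Z)
  if (is.null(colnames(X1))) colnames(X1) <- paste0("endo", seq_len(ncol(X1)))
  if (ncol(Z) < ncol(X1))
    stop("under-identified: fewer excluded instruments than endogenous ",
         "regressors", call. = FALSE)
  check_full_rank(cbind(X2, Z), "tsls_fit instrument set")
  fs <- first_stage(X1, X2, Z)
  Xhat <- cbind(fs$fitted, X2)
  Xorig <- cbind(X1, X2)
  qr_h <- check_full_rank(Xhat, "tsls_fit second stage")
  coef <- stats::setNames(qr.coef(qr_h, y), colnames(Xhat))
  resid <- y - drop(Xorig %*% coef)
  bread <- chol2inv(qr.R(qr_h))
  vc <- hc1_vcov(Xhat, resid, bread)
  dimnames(vc) <- list(colnames(Xhat), colnames(Xhat))
  iv_result(coef, vc, length(y), "tsls", residuals = resid,
            fitted = drop(Xorig %*% coef), first_stage_F = fs$F,
            first_stage = fs)
}

#' Wu-Hausman endogeneity test
#'
#' Regression-based (control-function) form: the outcome equation is
#' augmented with the first-stage residuals and the joint significance of
#' their coefficients is tested with a robust Wald F.  Rejection indicates
#' that OLS and IV estimands differ, i.e. endogeneity.  A contrast-form
#' variant (classic Hausman quadratic form in the coefficient difference,
#' classical covariances) is available for cross-checking.
#'
#' @param y,X1,X2,Z as in [tsls_fit()].
#' @param method `"control-function"` (default) or `"contrast"`.
#' @return list with `H` (statistic), `p`, `df1`, `df2`, `method`.
#' @export
wu_hausman <- function(y, X1, X2, Z, method = c("control-function",
                                                "contrast")) {
  method <- match.arg(method)
  X1 <- as.matrix(X1); X2 <- as.matrix(X2); Z <- as.matrix(Z)
  if (is.null(colnames(X1))) colnames(X1) <- paste0("endo", seq_len(ncol(X1)))
  fs <- first_stage(X1, X2, Z)
  q <- ncol(X1)
  if (method == "control-function") {
    Vhat <- fs$residuals
    colnames(Vhat) <- paste0("vhat_", colnames(X1))
    Xa <- cbind(X1, X2, Vhat)
    fit <- ols_fit(y, Xa)
    vi <- ncol(X1) + ncol(X2) + seq_len(q)
    b <- fit$coefficients[vi]
    V <- fit$vcov[vi, vi, drop = FALSE]
    H <- drop(t(b) %*% solve(V, b)) / q
    df2 <- length(y) - ncol(Xa)
  } else {
    ols <- ols_fit(y, cbind(X1, X2))
    iv <- tsls_fit(y, X1, X2, Z)
    nm <- colnames(X1)
    d <- iv$coefficients[nm] - ols$coefficients[nm]
    # classical covariances with the OLS error variance, per the classic form
    s2 <- sum(ols$residuals^2) / (length(y) - ncol(X1) - ncol(X2))
    Xh <- cbind(fs$fitted, X2); Xo <- cbind(X1, X2)
    Viv <- s2 * solve(crossprod(Xh))[seq_len(q), seq_len(q), drop = FALSE]
    Vol <- s2 * solve(crossprod(Xo))[seq_len(q), seq_len(q), drop = FALSE]
    H <- drop(t(d) %*% solve(Viv - Vol, d)) / q
    df2 <- length(y) - ncol(X1) - ncol(X2)
  }
  list(H = H, p = stats::pf(H, q, df2, lower.tail = FALSE), df1 = q,
       df2 = df2, method = method)
}

#' Wald test of coefficient equality across two specifications
#'
#' Default: paired case bootstrap.  Users are resampled with replacement;
#' both specifications are refitted on each replicate (so overlap between
#' the two estimation samples is accounted for) and the difference of the
#' named coefficient is tested against zero with a normal approximation
#' using the bootstrap standard error.  The analytic no-overlap variant
#' (variance = sum of squared standard errors) is also exposed.
#'
#' @param fit_a,fit_b fitted `iv_fit` objects (for the point difference and
#'   the analytic variant).
#' @param coefficient name of the coefficient to compare; must be present in
#'   both fits.
#' @param refit_a,refit_b functions `idx -> named coefficients` refitting
#'   each specification on a row index vector (required for the bootstrap).
#' @param n_index number of rows to resample over (the common sample size).
#' @param n_boot bootstrap replicates (default 500).
#' @param seed integer seed.
#' @param method `"bootstrap"` or `"analytic"`.
#' @return list `stat` (z), `p`, `difference`, `se`, `method`, `n_boot_ok`.
#' @export
wald_equality <- function(fit_a, fit_b, coefficient,
                          refit_a = NULL, refit_b = NULL, n_index = NULL,
                          n_boot = 500, seed = 1L,
                          method = c("bootstrap", "analytic")) {
  method <- match.arg(method)
  for (f in list(fit_a, fit_b))
    if (!coefficient %in% names(f$coefficients))
      stop("coefficient '", coefficient, "' not present in both fits",
           call. = FALSE)
  d <- fit_a$coefficients[[coefficient]] - fit_b$coefficients[[coefficient]]
  if (method == "analytic") {
    se <- sqrt(fit_a$robust_se[[coefficient]]^2 +
               fit_b$robust_se[[coefficient]]^2)
  } else {
    stopifnot(is.function(refit_a), is.function(refit_b),
              !is.null(n_index))
    set.seed(seed)
    diffs <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n_index, n_index, replace = TRUE)
      ca <- tryCatch(refit_a(idx), error = function(e) NULL)
      cb <- tryCatch(refit_b(idx), error = function(e) NULL)
      if (!is.null(ca) && !is.null(cb))
        diffs[b] <- ca[[coefficient]] - cb[[coefficient]]
    }
    diffs <- diffs[!is.na(diffs)]
    se <- stats::sd(diffs)
  }
  z <- if (abs(d) < 1e-12) 0 else d / se   # 0/0 (self-comparison) -> 0
  list(stat = z, p = 2 * stats::pnorm(-abs(z)), difference = d, se = se,
       method = method,
       n_boot_ok = if (method == "bootstrap") length(diffs) else NA_integer_)
}
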
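# Independent oracle implementations used to cross-check the package's code
# paths.  Deliberately written brute-force / closed-form, sharing no code
# with the implementations they check.

# brute-force in-coreness by iterative peeling on in-degree
oracle_in_coreness <- function(edges, nodes) {
  core <- stats::setNames(rep(0L, length(nodes)), nodes)
  k <- 0L
  active <- nodes
  e <- edges
  repeat {
    if (length(active) == 0) break
    repeat {
      indeg <- stats::setNames(rep(0L, length(active)), active)
      tab <- table(e$followee[e$followee %in% active &
                              e$follower %in% active])
      indeg[names(tab)] <- as.integer(tab)
      drop <- active[indeg < k]
      if (length(drop) == 0) break
      active <- setdiff(active, drop)
      e <- e[e$follower %in% active & e$followee %in% active, ]
    }
    core[active] <- k
    k <- k + 1L
  }
  core
}

# random simple directed graph as an edge data frame
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  from <- rep(seq_len(n), each = n)
  to <- rep(seq_len(n), times = n)
  keep <- from != to & stats::runif(n * n) < p
  data.frame(follower = from[keep], followee = to[keep])
}

# mixing-matrix assortativity assembled from explicit double loops
oracle_assortativity <- function(edges, labels) {
  cats <- sort(unique(unlist(labels)))
  e <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  for (i in seq_len(nrow(edges))) {
    lf <- labels[[as.character(edges$follower[i])]]
    lt <- labels[[as.character(edges$followee[i])]]
    e[lf, lt] <- e[lf, lt] + 1
  }
  e <- e / sum(e)
  a <- rowSums(e); b <- colSums(e)
  (sum(diag(e)) - sum(a * b)) / (1 - sum(a * b))
}

# hand product-limit estimator: S(t) at each distinct event time
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  S <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n_i <- sum(time >= ts[i])
    d_i <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    S[i] <- s
  }
  data.frame(time = ts, surv = S)
}

# Nelson-Aalen cumulative hazard on its event-time grid
oracle_nelson_aalen <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  H <- cumsum(vapply(ts, function(t)
    sum(time == t & event == 1) / sum(time >= t), numeric(1)))
  data.frame(time = ts, H = H)
}

# pure-R Aalen least-squares increments, O(K * n p^2) direct form
oracle_aalen <- function(time, event, X) {
  X <- cbind(1, as.matrix(X))
  ts <- sort(unique(time[event == 1]))
  p <- ncol(X)
  dB <- matrix(NA_real_, length(ts), p)
  for (k in seq_along(ts)) {
    at_risk <- time >= ts[k]
    Xr <- X[at_risk, , drop = FALSE]
    dn <- as.numeric(time == ts[k] & event == 1)[at_risk]
    dB[k, ] <- tryCatch(solve(crossprod(Xr), crossprod(Xr, dn)),
                        error = function(e) rep(NA_real_, p))
  }
  ok <- stats::complete.cases(dB)
  list(times = ts[ok], B = apply(dB[ok, , drop = FALSE], 2, cumsum))
}

# exactly-identified IV slope through the Wald ratio (no covariates)
oracle_wald_ratio <- function(y, x, z) {
  stats::cov(z, y) / stats::cov(z, x)
}

# a small deterministic panel-free trait/outcome DGP used by estimator
# calibration tests: Y = beta x + gamma u + e, X = pi z + delta u + v
toy_iv_data <- function(n, beta = 0.3, gamma = 1, pi_z = 0.6, delta = 0.8,
                        seed = 1) {
  set.seed(seed)
  u <- stats::rnorm(n); z <- stats::rnorm(n); v <- stats::rnorm(n)
  x <- pi_z * z + delta * u + v
  y <- beta * x + gamma * u + stats::rnorm(n)
  data.frame(y = y, x = x, z = z, u = u)
}
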
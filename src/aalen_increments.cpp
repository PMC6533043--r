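// Least-squares increments for Aalen's additive hazards model.
//
// At each distinct event time t_k the increment of the cumulative
// regression function is dB(t_k) = (X_R' X_R)^{-1} X_R' dN(t_k), where X_R
// stacks the covariate rows of subjects still at risk (time >= t_k) and
// dN counts the events at t_k (ties processed together).  Subjects are
// processed in increasing time order and X'X is downdated as subjects
// leave the risk set, so the whole path costs O(n p^2 + K p^3).
// Estimation stops at the first event time whose at-risk design is
// singular or has reciprocal condition number below 1/cond_cap (standard
// truncation at the tail of the risk set).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::List aalen_increments_cpp(const arma::vec& time,
                                const arma::ivec& event,
                                const arma::mat& X,
                                double cond_cap) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::uvec ord = arma::stable_sort_index(time);

  // distinct event times, increasing
  std::vector<double> etimes;
  for (arma::uword i = 0; i < n; ++i) {
    arma::uword s = ord(i);
    if (event(s) == 1 &&
        (etimes.empty() || time(s) > etimes.back()))
      etimes.push_back(time(s));
  }
  const arma::uword K = etimes.size();

  arma::mat XtX = X.t() * X;          // risk set at t = 0 is everyone
  arma::mat dB(K, p, arma::fill::zeros);
  arma::vec atrisk(K, arma::fill::zeros);
  arma::vec nevent(K, arma::fill::zeros);
  arma::uword ptr = 0;                 // subjects already out of the risk set
  arma::uword used = 0;
  bool truncated = false;

  for (arma::uword k = 0; k < K; ++k) {
    double t = etimes[k];
    while (ptr < n && time(ord(ptr)) < t) {
      XtX -= X.row(ord(ptr)).t() * X.row(ord(ptr));
      ++ptr;
    }
    arma::vec xdn(p, arma::fill::zeros);
    double d = 0.0;
    for (arma::uword j = ptr; j < n && time(ord(j)) == t; ++j) {
      arma::uword s = ord(j);
      if (event(s) == 1) {
        xdn += X.row(s).t();
        d += 1.0;
      }
    }
    double rc = arma::rcond(arma::symmatu(XtX));
    if (!std::isfinite(rc) || rc < 1.0 / cond_cap) {
      truncated = true;
      break;
    }
    arma::vec db = arma::solve(arma::symmatu(XtX), xdn,
                               arma::solve_opts::likely_sympd);
    dB.row(k) = db.t();
    atrisk(k) = static_cast<double>(n - ptr);
    nevent(k) = d;
    ++used;
  }

  arma::mat dB_out(used, p);
  arma::vec atrisk_out(used), nevent_out(used);
  if (used > 0) {
    dB_out = dB.rows(0, used - 1);
    atrisk_out = atrisk.subvec(0, used - 1);
    nevent_out = nevent.subvec(0, used - 1);
  }
  return Rcpp::List::create(
      Rcpp::Named("times") = std::vector<double>(etimes.begin(),
                                                 etimes.begin() + used),
      Rcpp::Named("dB") = dB_out,
      Rcpp::Named("n_at_risk") = atrisk_out,
      Rcpp::Named("n_events") = nevent_out,
      Rcpp::Named("used") = static_cast<int>(used),
      Rcpp::Named("truncated") = truncated);
}
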
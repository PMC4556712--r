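// Graphical lasso: L1-penalized Gaussian maximum-likelihood estimation of
// the inverse covariance matrix, by block coordinate descent on the
// covariance estimate W (Friedman-Hastie-Tibshirani algorithm). Each column
// update solves a lasso problem by cyclic coordinate descent. Warm starts
// (W and the regression coefficients B) are supported so that a sequence of
// penalties, e.g. during a bisection search on the support size, is cheap.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat &S, double lambda,
                      Rcpp::Nullable<Rcpp::NumericMatrix> W_init,
                      Rcpp::Nullable<Rcpp::NumericMatrix> B_init,
                      int maxit_outer = 100, int maxit_inner = 500,
                      double tol = 1e-4) {
  const uword p = S.n_rows;
  mat W, B;
  if (W_init.isNotNull()) {
    W = Rcpp::as<mat>(W_init.get());
    W.diag() = S.diag() + lambda; // diagonal is fixed by the stationarity eqs
  } else {
    W = S;
    W.diag() += lambda;
  }
  if (B_init.isNotNull()) B = Rcpp::as<mat>(B_init.get());
  else B = zeros(p, p);

  if (p == 1) {
    mat Wi = 1.0 / W;
    return Rcpp::List::create(Rcpp::Named("w") = W, Rcpp::Named("wi") = Wi,
                              Rcpp::Named("beta") = B,
                              Rcpp::Named("niter") = 0,
                              Rcpp::Named("converged") = true);
  }

  double off_mean = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j) off_mean += std::fabs(S(i, j));
  off_mean /= (p * (p - 1) / 2.0);
  const double thr_outer = tol * std::max(off_mean, 1e-12);
  const double thr_inner = 0.1 * thr_outer;

  int iter = 0;
  bool converged = false;
  uvec all = regspace<uvec>(0, p - 1);

  for (iter = 1; iter <= maxit_outer; ++iter) {
    double dw_max = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx = find(all != j);
      mat W11 = W(idx, idx);
      vec s12 = S.col(j);
      s12 = s12(idx);
      vec beta = B.col(j);
      beta = beta(idx);

      for (int in_it = 0; in_it < maxit_inner; ++in_it) {
        double dmax = 0.0;
        for (uword k = 0; k < p - 1; ++k) {
          double wkk = W11(k, k);
          double r = s12(k) - dot(W11.col(k), beta) + wkk * beta(k);
          double bnew = soft(r, lambda) / wkk;
          double d = bnew - beta(k);
          if (d != 0.0) {
            beta(k) = bnew;
            double ad = std::fabs(d);
            if (ad > dmax) dmax = ad;
          }
        }
        if (dmax < thr_inner) break;
      }

      vec w12 = W11 * beta;
      double dj = 0.0;
      for (uword k = 0; k < p - 1; ++k) {
        double d = std::fabs(W(idx(k), j) - w12(k));
        if (d > dj) dj = d;
      }
      if (dj > dw_max) dw_max = dj;
      for (uword k = 0; k < p - 1; ++k) {
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
      vec bfull = zeros(p);
      bfull(idx) = beta;
      B.col(j) = bfull;
    }
    if (!W.is_finite()) { // divergence (possible for tiny lambda, n < p)
      return Rcpp::List::create(
          Rcpp::Named("w") = W, Rcpp::Named("wi") = R_NilValue,
          Rcpp::Named("beta") = B, Rcpp::Named("support") = R_NilValue,
          Rcpp::Named("niter") = iter, Rcpp::Named("converged") = false,
          Rcpp::Named("finite") = false);
    }
    if (dw_max < thr_outer) { converged = true; break; }
  }

  // recover the concentration matrix from the final (W, B)
  mat Theta = zeros(p, p);
  for (uword j = 0; j < p; ++j) {
    uvec idx = find(all != j);
    vec beta = B.col(j);
    beta = beta(idx);
    uvec jv(1);
    jv(0) = j;
    vec w12 = W.submat(idx, jv);
    double denom = W(j, j) - dot(w12, beta);
    if (denom < 1e-12) denom = 1e-12; // guard against loss of PD-ness
    double t22 = 1.0 / denom;
    Theta(j, j) = t22;
    for (uword k = 0; k < p - 1; ++k) Theta(idx(k), j) = -beta(k) * t22;
  }
  Theta = 0.5 * (Theta + Theta.t());

  // exact-zero support from the lasso coefficients (symmetric by OR)
  mat nz = conv_to<mat>::from(B != 0);
  mat support = clamp(nz + nz.t(), 0.0, 1.0);
  support.diag().zeros();

  return Rcpp::List::create(
      Rcpp::Named("w") = W, Rcpp::Named("wi") = Theta,
      Rcpp::Named("beta") = B, Rcpp::Named("support") = support,
      Rcpp::Named("niter") = iter, Rcpp::Named("converged") = converged,
      Rcpp::Named("finite") = true);
}
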
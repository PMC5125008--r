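// Dual coordinate descent for the L1-loss (hinge) linear SVM *without* a
// solver-internal bias term:
//
//   min_w  (1/2) ||w||^2 + C * sum_i max(0, 1 - y_i w' x_i)
//
// The offset is expected to be carried by an all-ones constant column of X,
// so the dual is a pure box-constrained QP, 0 <= alpha_i <= C, with no
// equality constraint.  Coordinates are swept in a randomized order (a
// self-contained LCG with a fixed seed — R's RNG stream is untouched and
// results are bit-reproducible for fixed inputs), with the usual shrinking
// heuristic on the projected gradient.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Xt: m x n matrix (features in rows, one subject per column, constant
//     feature included by the caller); y: +1/-1 labels; C > 0.
// tol: stopping tolerance on the projected-gradient range; max_pass:
//     hard cap on outer sweeps.
// [[Rcpp::export(name = ".dcdLinearSvm")]]
Rcpp::List dcd_linear_svm(const arma::mat& Xt, const arma::vec& y,
                          const double C, const double tol,
                          const int max_pass) {
  const arma::uword n = Xt.n_cols;
  const arma::uword m = Xt.n_rows;
  if (y.n_elem != n) Rcpp::stop("length(y) must equal ncol(Xt)");

  arma::vec alpha(n, arma::fill::zeros);
  arma::vec w(m, arma::fill::zeros);
  arma::vec Qii(n);
  for (arma::uword i = 0; i < n; ++i) Qii(i) = arma::dot(Xt.col(i), Xt.col(i));

  std::vector<arma::uword> active(n);
  for (arma::uword i = 0; i < n; ++i) active[i] = i;
  double PGmax_old = arma::datum::inf;
  double PGmin_old = -arma::datum::inf;

  // fixed-seed linear congruential generator (Park-Miller) for the
  // per-pass coordinate shuffle; independent of R's RNG
  unsigned long long lcg = 88172645463325252ULL;
  auto nextRand = [&lcg]() {
    lcg = (6364136223846793005ULL * lcg + 1442695040888963407ULL);
    return static_cast<double>(lcg >> 11) / 9007199254740992.0;
  };

  int pass = 0;
  int n_pass = 0;
  for (pass = 0; pass < max_pass; ++pass) {
    double PGmax_new = -arma::datum::inf;
    double PGmin_new = arma::datum::inf;
    ++n_pass;

    // Fisher-Yates shuffle of the active set
    for (std::size_t s = active.size(); s > 1; --s) {
      std::size_t j = static_cast<std::size_t>(nextRand() * s);
      if (j >= s) j = s - 1;
      std::swap(active[s - 1], active[j]);
    }

    for (std::size_t s = 0; s < active.size(); ++s) {
      const arma::uword i = active[s];
      const double yi = y(i);
      const double G = yi * arma::dot(w, Xt.col(i)) - 1.0;

      double PG = 0.0;
      bool shrink = false;
      if (alpha(i) == 0.0) {
        if (G > PGmax_old) shrink = true;
        else if (G < 0.0) PG = G;
      } else if (alpha(i) == C) {
        if (G < PGmin_old) shrink = true;
        else if (G > 0.0) PG = G;
      } else {
        PG = G;
      }
      if (shrink) {
        active[s] = active.back();
        active.pop_back();
        --s;
        continue;
      }
      if (PG > PGmax_new) PGmax_new = PG;
      if (PG < PGmin_new) PGmin_new = PG;
      if (std::fabs(PG) > 1e-12) {
        const double old = alpha(i);
        double a = old - G / Qii(i);
        if (a < 0.0) a = 0.0; else if (a > C) a = C;
        alpha(i) = a;
        if (a != old) w += (a - old) * yi * Xt.col(i);
      }
    }

    if (PGmax_new - PGmin_new <= tol) {
      if (active.size() == n) break;
      // converged on the shrunk set: re-activate everything and re-check
      active.resize(n);
      for (arma::uword i = 0; i < n; ++i) active[i] = i;
      PGmax_old = arma::datum::inf;
      PGmin_old = -arma::datum::inf;
      continue;
    }
    PGmax_old = (PGmax_new <= 0.0) ? arma::datum::inf : PGmax_new;
    PGmin_old = (PGmin_new >= 0.0) ? -arma::datum::inf : PGmin_new;
  }

  return Rcpp::List::create(Rcpp::Named("w") = w,
                            Rcpp::Named("alpha") = alpha,
                            Rcpp::Named("passes") = n_pass,
                            Rcpp::Named("converged") = pass < max_pass);
}
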
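// Alternating-update engine for CP decomposition: HALS (nonnegative) or
// ALS (unconstrained) sweeps over the three modes, with the reconstruction
// error tracked per sweep via inner products. Called from cp_fit().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Khatri-Rao product with column (b, a) layout: row a + nA*b holds
// A.row(a) % B.row(b); matches R's column-major unfoldings.
static mat khatri_rao(const mat& A, const mat& B) {
  const uword nA = A.n_rows, nB = B.n_rows, R = A.n_cols;
  mat out(nA * nB, R);
  for (uword r = 0; r < R; ++r) {
    mat col(out.colptr(r), nA, nB, false, true);
    col = A.col(r) * B.col(r).t();
  }
  return out;
}

// [[Rcpp::export(name = ".cp_engine")]]
Rcpp::List cp_engine(const arma::mat& X1, const arma::mat& X2,
                     const arma::mat& X3, arma::mat U, arma::mat V,
                     arma::mat W, const bool nonneg, const double tol,
                     const int max_iter, const double normX2) {
  const uword R = U.n_cols;
  std::vector<const mat*> Xn = {&X1, &X2, &X3};
  std::vector<mat*> fac = {&U, &V, &W};
  std::vector<mat> gram(3);
  for (int n = 0; n < 3; ++n) gram[n] = (*fac[n]).t() * (*fac[n]);

  std::vector<double> err_hist;
  double err_prev = datum::inf;
  bool converged = false;
  mat M, G;

  for (int it = 0; it < max_iter; ++it) {
    for (int n = 0; n < 3; ++n) {
      const int o1 = (n == 0) ? 1 : 0;
      const int o2 = (n == 2) ? 1 : 2;
      mat KR = khatri_rao(*fac[o1], *fac[o2]);
      M = (*Xn[n]) * KR;
      G = gram[o1] % gram[o2];
      mat& A = *fac[n];
      if (nonneg) {
        for (uword r = 0; r < R; ++r) {
          const double gr = G(r, r);
          if (gr <= datum::eps) {
            // deterministic revival of a starved column
            for (uword i = 0; i < A.n_rows; ++i)
              A(i, r) = 1e-10 * (1.0 + double(i) / A.n_rows);
            continue;
          }
          vec upd = (M.col(r) - A * G.col(r) + A.col(r) * gr) / gr;
          A.col(r) = clamp(upd, 0.0, datum::inf);
        }
      } else {
        mat Greg = G + 1e-12 * G.max() * eye(R, R);
        A = solve(Greg, M.t(), solve_opts::likely_sympd).t();
      }
      gram[n] = A.t() * A;
    }
    const double inner = accu(W % M);
    const double normhat2 = accu(gram[0] % gram[1] % gram[2]);
    double err = std::sqrt(std::max(0.0, normX2 - 2 * inner + normhat2)) /
      std::sqrt(normX2);
    err_hist.push_back(err);
    if (std::isfinite(err_prev) && std::fabs(err_prev - err) < tol) {
      err_prev = err;
      converged = true;
      break;
    }
    err_prev = err;
    // balance column norms across modes (reconstruction unchanged)
    rowvec n1 = sqrt(sum(square(U), 0));
    rowvec n2 = sqrt(sum(square(V), 0));
    rowvec n3 = sqrt(sum(square(W), 0));
    rowvec lam3 = pow(n1 % n2 % n3, 1.0 / 3.0);
    for (uword r = 0; r < R; ++r) {
      if (n1(r) > 0) U.col(r) *= lam3(r) / n1(r);
      if (n2(r) > 0) V.col(r) *= lam3(r) / n2(r);
      if (n3(r) > 0) W.col(r) *= lam3(r) / n3(r);
    }
    for (int n = 0; n < 3; ++n) gram[n] = (*fac[n]).t() * (*fac[n]);
  }
  return Rcpp::List::create(
    Rcpp::Named("U") = U, Rcpp::Named("V") = V, Rcpp::Named("W") = W,
    Rcpp::Named("err_hist") = err_hist,
    Rcpp::Named("converged") = converged);
}
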
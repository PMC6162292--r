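// Profile-likelihood kernel for the AR(1) multivariate-normal polynomial
// association model. For a fixed AR(1) correlation rho the per-group
// polynomial coefficients and the residual scale have closed forms built
// from the tridiagonal quadratic form
//   Q(rho,U,V) = U' R(rho)^{-1} V
//              = [ (U1V1 + UmVm) - rho * sum_{t<m}(U_t V_{t+1} + U_{t+1} V_t)
//                  + (1+rho^2) * sum_{1<t<m} U_t V_t ] / (1 - rho^2),
// so every Q needed along the rho profile decomposes into three
// rho-independent cross-sums computed once per dataset.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct QParts {
  mat c0, c1, c2;  // for a pair of column sets: Q = (c0 - rho*c1 + (1+rho^2)*c2)/(1-rho^2)
};

// Cross-sums for Q(rho, A_i, B_j) over all column pairs of A (m x p) and B (m x q).
QParts q_parts(const mat& A, const mat& B) {
  const uword m = A.n_rows;
  QParts qp;
  qp.c0 = A.row(0).t() * B.row(0) + A.row(m - 1).t() * B.row(m - 1);
  qp.c1 = zeros<mat>(A.n_cols, B.n_cols);
  qp.c2 = zeros<mat>(A.n_cols, B.n_cols);
  for (uword t = 0; t + 1 < m; ++t)
    qp.c1 += A.row(t).t() * B.row(t + 1) + A.row(t + 1).t() * B.row(t);
  for (uword t = 1; t + 1 < m; ++t)
    qp.c2 += A.row(t).t() * B.row(t);
  return qp;
}

inline mat q_eval(const QParts& qp, double rho) {
  return (qp.c0 - rho * qp.c1 + (1.0 + rho * rho) * qp.c2) / (1.0 - rho * rho);
}

struct SuffStats {
  uword n, m, G, p;
  QParts basis;                 // Q parts for basis x basis (p x p)
  std::vector<QParts> tb;      // per group: Q parts for T_g x basis (1 x p)
  std::vector<double> s0, s1, s2;  // per group: sum_i of the y_i'R^-1 y_i parts
  std::vector<double> ng;
};

SuffStats make_stats(const mat& Y, const ivec& group, int G, const mat& basis) {
  SuffStats st;
  st.n = Y.n_rows; st.m = Y.n_cols; st.G = (uword)G; st.p = basis.n_cols;
  st.basis = q_parts(basis, basis);
  st.tb.resize(G); st.s0.assign(G, 0.0); st.s1.assign(G, 0.0);
  st.s2.assign(G, 0.0); st.ng.assign(G, 0.0);
  mat Tg = zeros<mat>(st.m, G);
  for (uword i = 0; i < st.n; ++i) {
    const int g = group[i];
    const rowvec yi = Y.row(i);
    Tg.col(g) += yi.t();
    st.ng[g] += 1.0;
    st.s0[g] += yi[0] * yi[0] + yi[st.m - 1] * yi[st.m - 1];
    for (uword t = 0; t + 1 < st.m; ++t) st.s1[g] += 2.0 * yi[t] * yi[t + 1];
    for (uword t = 1; t + 1 < st.m; ++t) st.s2[g] += yi[t] * yi[t];
  }
  for (int g = 0; g < G; ++g)
    st.tb[g] = q_parts(Tg.col(g), basis);
  return st;
}

// Evaluate the profiled log-likelihood at rho; optionally return beta, sigma2.
double profile_at(const SuffStats& st, double rho,
                  mat* beta_out, double* sigma2_out) {
  const double one_m_r2 = 1.0 - rho * rho;
  const mat Qb = q_eval(st.basis, rho);
  double rss = 0.0;
  mat beta(st.p, st.G);
  for (uword g = 0; g < st.G; ++g) {
    const vec b = q_eval(st.tb[g], rho).t();
    const mat A = st.ng[g] * Qb;
    const vec bg = solve(A, b, solve_opts::fast);
    const double syy = (st.s0[g] - rho * st.s1[g]
                        + (1.0 + rho * rho) * st.s2[g]) / one_m_r2;
    rss += syy - dot(b, bg);
    beta.col(g) = bg;
  }
  const double mN = (double)(st.m * st.n);
  double sigma2 = rss / mN;
  if (sigma2 < 1e-12) sigma2 = 1e-12;  // floor keeps the log defined on noiseless fits
  const double ll = -0.5 * mN * std::log(2.0 * M_PI)
    - 0.5 * (double)st.n * ((st.m - 1.0) * std::log(one_m_r2)
                            + (double)st.m * std::log(sigma2))
    - 0.5 * mN;
  if (beta_out) *beta_out = beta;
  if (sigma2_out) *sigma2_out = sigma2;
  return ll;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericVector mptga_profile_cpp(const arma::mat& Y,
                                      const arma::ivec& group, int G,
                                      const arma::mat& basis,
                                      const arma::vec& rho) {
  SuffStats st = make_stats(Y, group, G, basis);
  Rcpp::NumericVector out(rho.n_elem);
  for (uword k = 0; k < rho.n_elem; ++k)
    out[k] = profile_at(st, rho[k], nullptr, nullptr);
  return out;
}

// [[Rcpp::export]]
Rcpp::List mptga_fit_cpp(const arma::mat& Y, const arma::ivec& group, int G,
                         const arma::mat& basis, double rho) {
  SuffStats st = make_stats(Y, group, G, basis);
  mat beta;
  double sigma2;
  const double ll = profile_at(st, rho, &beta, &sigma2);
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("sigma2") = sigma2,
                            Rcpp::Named("loglik") = ll);
}
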
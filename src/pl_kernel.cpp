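// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Penalized pseudo-log-likelihood of the phenotype-conditioned genotype
// model, negated and on the per-sample scale, plus its exact gradient.
//
// Parameterization: genotype level 0 is the zero-parameter reference, so the
// free levels are a = 1..L (L = 1 dominant, L = 2 genotypic).  Column (i,a)
// of the n x mL indicator matrix B is 1 when sample k carries level a at SNP
// i.  Fields h_l are length-mL vectors; couplings J_l are mL x mL symmetric
// matrices with zero diagonal (same-SNP) blocks, stored fully; `upper` and
// `lower` hold the 0-based linear indices of the two copies of each free
// off-diagonal block entry (i < j).
//
// theta = [h0, h1, Ju0, Ju1]; the J blocks are absent when lam2 is +Inf
// (interactions switched off).
//
// The site linear predictor eta[k,(i,a)] = H_i(a | a^k; y_k) is
//   h0 + (B J0) + y_k * (h1 + (B J1)),
// the per-site denominator is 1 + sum_a exp(eta), and the objective is
//   f(theta) = -(1/n) sum_{k,i} log Pr(a_i^k | a_{j != i}^k, y_k)
//              + (lam1/2)|h|^2 + (lam2/2)|Ju|^2.
// Because J_ij(a,b) enters both the site-i and the site-j conditional, its
// exact derivative carries both contributions (D + D^t below).
// [[Rcpp::export(name = ".plKernel")]]
Rcpp::List plKernel(const arma::vec& theta, const arma::mat& B,
                    const arma::vec& y, int L,
                    const arma::uvec& upper, const arma::uvec& lower,
                    double lam1, double lam2, bool wantGrad) {
  const int n = B.n_rows, mL = B.n_cols, m = mL / L;
  const int nJ = upper.n_elem;
  const bool noJ = !std::isfinite(lam2);
  vec h0 = theta.subvec(0, mL - 1), h1 = theta.subvec(mL, 2 * mL - 1);
  mat J0(mL, mL, fill::zeros), J1(mL, mL, fill::zeros);
  vec Ju0, Ju1;
  if (!noJ && nJ > 0) {
    Ju0 = theta.subvec(2 * mL, 2 * mL + nJ - 1);
    Ju1 = theta.subvec(2 * mL + nJ, 2 * mL + 2 * nJ - 1);
    J0.elem(upper) = Ju0; J0.elem(lower) = Ju0;
    J1.elem(upper) = Ju1; J1.elem(lower) = Ju1;
  }
  mat eta = B * J0 + repmat(h0.t(), n, 1)
          + (B * J1 + repmat(h1.t(), n, 1)).eval().each_col() % y;
  mat ex = exp(clamp(eta, -700.0, 700.0));
  mat den(n, m);
  for (int i = 0; i < m; ++i) {
    vec d(n, fill::ones);
    for (int a = 0; a < L; ++a) d += ex.col(i * L + a);
    den.col(i) = d;
  }
  double ll = accu(B % eta) - accu(log(den));
  double pen = 0.5 * lam1 * (dot(h0, h0) + dot(h1, h1));
  if (!noJ && nJ > 0) pen += 0.5 * lam2 * (dot(Ju0, Ju0) + dot(Ju1, Ju1));
  double f = -ll / n + pen;
  if (!wantGrad) return Rcpp::List::create(Rcpp::Named("value") = f);
  mat P(n, mL);
  for (int i = 0; i < m; ++i)
    for (int a = 0; a < L; ++a) P.col(i * L + a) = ex.col(i * L + a) / den.col(i);
  mat Rm = B - P;
  vec gh0 = -sum(Rm, 0).t() / n + lam1 * h0;
  vec gh1 = -(Rm.t() * y) / n + lam1 * h1;
  if (noJ || nJ == 0)
    return Rcpp::List::create(Rcpp::Named("value") = f,
                              Rcpp::Named("grad") = join_cols(gh0, gh1));
  mat D0 = Rm.t() * B;
  mat S0 = D0 + D0.t();
  mat D1 = Rm.t() * (B.each_col() % y);
  mat S1 = D1 + D1.t();
  vec gJ0 = -S0.elem(upper) / n + lam2 * Ju0;
  vec gJ1 = -S1.elem(upper) / n + lam2 * Ju1;
  return Rcpp::List::create(
    Rcpp::Named("value") = f,
    Rcpp::Named("grad") = join_cols(join_cols(gh0, gh1), join_cols(gJ0, gJ1)));
}

// Trapezoidal Bayes phenotype prediction under the PL factorization.
// C0, C1: per-sample site linear coefficients (n x mL) for the y^0 and y^1
// parts of H_i; B: observed-level indicators; pts/tw: quadrature grid and
// weights; logPrior: log Normal(mu, sigma2) density at pts.
// [[Rcpp::export(name = ".bayesKernel")]]
arma::vec bayesKernel(const arma::mat& B, const arma::mat& C0,
                      const arma::mat& C1, int L, const arma::vec& pts,
                      const arma::vec& tw, const arma::vec& logPrior) {
  const int n = B.n_rows, mL = B.n_cols, m = mL / L, nG = pts.n_elem;
  vec o0 = sum(B % C0, 1), o1 = sum(B % C1, 1);
  mat lp(n, nG);
  for (int g = 0; g < nG; ++g) {
    mat ex = exp(clamp(C0 + pts[g] * C1, -700.0, 700.0));
    vec lse(n, fill::zeros);
    for (int i = 0; i < m; ++i) {
      vec d(n, fill::ones);
      for (int a = 0; a < L; ++a) d += ex.col(i * L + a);
      lse += log(d);
    }
    lp.col(g) = o0 + pts[g] * o1 - lse + logPrior[g];
  }
  vec mx = max(lp, 1);
  lp.each_col() -= mx;
  mat w = exp(lp);
  vec den = w * tw;
  vec num = w * (tw % pts);
  return num / den;
}
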
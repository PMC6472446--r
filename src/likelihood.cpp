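// Exact probability of biallelic allele-count patterns under the
// two-population multispecies coalescent, by analytic integration over
// gene trees and substitution histories.
//
// Partial likelihoods F(n, r) evolve up a branch by dF/dt = A F where A
// combines pairwise coalescence (rate 1/(2N) per lineage pair, N = Ne*mu)
// and per-lineage two-state mutation (u: red->green, v: green->red).
// At the species-tree root the two tables are pooled (hypergeometric
// mixing of red counts) and contracted against the root functional w,
// the probability of the pooled configuration coalescing to the most
// recent common ancestor whose state is drawn from stationarity.

#include <RcppArmadillo.h>
#include "state_space.h"
using namespace arma;

// [[Rcpp::export]]
arma::mat build_generator_cpp(int nmax, double coal_pair_rate, double u,
                              double v) {
  int D = state_dim(nmax);
  mat A(D, D, fill::zeros);
  for (int n = 1; n <= nmax; ++n) {
    double cn2 = 0.5 * n * (n - 1);
    for (int r = 0; r <= n; ++r) {
      int i = state_index(n, r);
      A(i, i) -= cn2 * coal_pair_rate + r * u + (n - r) * v;
      if (r >= 1) A(i, state_index(n, r - 1)) += r * u;
      if (r < n) A(i, state_index(n, r + 1)) += (n - r) * v;
      if (n < nmax) {
        // inflow from level n+1: a coalescence merges two same-coloured
        // lineages; the merged ancestor is uniform among the n survivors
        double cnp = 0.5 * (n + 1) * n * coal_pair_rate;
        A(i, state_index(n + 1, r + 1)) += cnp * ((double)r / n);
        A(i, state_index(n + 1, r)) += cnp * ((double)(n - r) / n);
      }
    }
  }
  return A;
}

// Root functional w(n, r): probability of the observed data conditional on
// n pooled lineages with r reds entering the root population, integrating
// the coalescent down to the MRCA with stationary state frequencies.
// Solved level-by-level as tridiagonal systems (w is the left null vector
// of the root-branch generator with boundary at n = 1).
// [[Rcpp::export]]
arma::vec root_functional_cpp(int nmax, double coal_pair_rate, double u,
                              double v) {
  int D = state_dim(nmax);
  vec w(D, fill::zeros);
  w(0) = 1.0;
  double pi_green = u / (u + v), pi_red = v / (u + v);
  if (nmax >= 1) {
    w(state_index(1, 0)) = pi_green;
    w(state_index(1, 1)) = pi_red;
  }
  std::vector<double> diag(nmax + 1), upper(nmax + 1), lower(nmax + 1),
      rhs(nmax + 1);
  for (int n = 2; n <= nmax; ++n) {
    double cn2 = 0.5 * n * (n - 1) * coal_pair_rate;
    for (int r = 0; r <= n; ++r) {
      diag[r] = cn2 + r * u + (n - r) * v;
      upper[r] = -(r + 1) * u;        // coefficient of w(n, r+1)
      lower[r] = -(n - r + 1) * v;    // coefficient of w(n, r-1)
      double inflow = 0.0;
      if (r >= 1)
        inflow += ((double)(r - 1) / (n - 1)) * w(state_index(n - 1, r - 1));
      if (r <= n - 1)
        inflow += ((double)(n - 1 - r) / (n - 1)) * w(state_index(n - 1, r));
      rhs[r] = cn2 * inflow;
    }
    // Thomas algorithm (the system is diagonally dominant)
    for (int r = 1; r <= n; ++r) {
      double f = lower[r] / diag[r - 1];
      diag[r] -= f * upper[r - 1];
      rhs[r] -= f * rhs[r - 1];
    }
    w(state_index(n, n)) = rhs[n] / diag[n];
    for (int r = n - 1; r >= 0; --r)
      w(state_index(n, r)) =
          (rhs[r] - upper[r] * w(state_index(n, r + 1))) / diag[r];
  }
  return w;
}

// Pooling weights at the root: combining independent branch-top tables
// indexed by within-branch red counts into the pooled table uses the
// hypergeometric probability of the within-branch split.
static mat pooling_matrix(int n1max, int n2max, const vec& w) {
  int D1 = state_dim(n1max), D2 = state_dim(n2max);
  mat W(D1, D2, fill::zeros);
  W(0, 0) = 1.0;
  for (int na = 0; na <= n1max; ++na)
    for (int ra = 0; ra <= na; ++ra)
      for (int nb = 0; nb <= n2max; ++nb)
        for (int rb = 0; rb <= nb; ++rb) {
          if (na + nb == 0) continue;
          double lw = Rf_lchoose(na, ra) + Rf_lchoose(nb, rb) -
                      Rf_lchoose(na + nb, ra + rb);
          W(state_index(na, ra), state_index(nb, rb)) =
              std::exp(lw) * w(state_index(na + nb, ra + rb));
        }
  return W;
}

// Full matrix of pattern probabilities: entry [state_index(n1, r1),
// state_index(n2, r2)] is the exact probability of observing the
// allele-count pattern ((n1, r1), (n2, r2)); sample sizes up to
// (n1max, n2max) are all covered by a single evaluation.
// [[Rcpp::export]]
arma::mat pattern_prob_matrix_cpp(int n1max, int n2max, double t,
                                  double Nroot, double Nd1, double Nd2,
                                  double u, double v) {
  mat P1, P2;
  if (n1max > 0) {
    mat A1 = build_generator_cpp(n1max, 1.0 / (2.0 * Nd1), u, v);
    P1 = expmat(A1 * t);
  } else {
    P1 = mat(1, 1, fill::ones);
  }
  if (n2max > 0) {
    mat A2 = build_generator_cpp(n2max, 1.0 / (2.0 * Nd2), u, v);
    P2 = expmat(A2 * t);
  } else {
    P2 = mat(1, 1, fill::ones);
  }
  vec w = root_functional_cpp(n1max + n2max, 1.0 / (2.0 * Nroot), u, v);
  mat W = pooling_matrix(n1max, n2max, w);
  return P1.t() * W * P2;
}

// Log-likelihood of one pair's aggregated pattern table.
// patterns: integer matrix with columns n1, r1, n2, r2, weight.
// correction: 0 = none, 1 = per-site variable-only conditioning,
//             2 = SNAPP-style maximum-sample-size conditioning.
// [[Rcpp::export]]
double pair_loglik_cpp(const arma::imat& patterns, double t, double Nroot,
                       double Nd1, double Nd2, double u, double v,
                       int correction) {
  if (patterns.n_rows == 0) return 0.0;
  int n1max = patterns.col(0).max(), n2max = patterns.col(2).max();
  mat M;
  try {
    M = pattern_prob_matrix_cpp(n1max, n2max, t, Nroot, Nd1, Nd2, u, v);
  } catch (...) {
    return -datum::inf;
  }
  if (!M.is_finite()) return -datum::inf;
  double ll = 0.0, total_weight = 0.0;
  for (uword i = 0; i < patterns.n_rows; ++i) {
    int n1 = patterns(i, 0), r1 = patterns(i, 1);
    int n2 = patterns(i, 2), r2 = patterns(i, 3);
    double wgt = patterns(i, 4);
    double p = M(state_index(n1, r1), state_index(n2, r2));
    if (correction == 1) {
      double pc = M(state_index(n1, 0), state_index(n2, 0)) +
                  M(state_index(n1, n1), state_index(n2, n2));
      p /= (1.0 - pc);
    }
    if (p <= 0.0 || !std::isfinite(p)) return -datum::inf;
    ll += wgt * std::log(p);
    total_weight += wgt;
  }
  if (correction == 2) {
    double pc = M(state_index(n1max, 0), state_index(n2max, 0)) +
                M(state_index(n1max, n1max), state_index(n2max, n2max));
    double pv = 1.0 - pc;
    if (pv <= 0.0) return -datum::inf;
    ll -= total_weight * std::log(pv);
  }
  return ll;
}

// Dense matrix exponential (used by branch propagation at the R level).
// [[Rcpp::export]]
arma::mat expm_cpp(const arma::mat& A) { return expmat(A); }
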
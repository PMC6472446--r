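#ifndef CODIV_PAIR_ENGINE_H
#define CODIV_PAIR_ENGINE_H

// Fast repeated likelihood evaluation for one pair during MCMC.
//
// The branch operator exp(A t) is needed only at the observed leaf
// states, and most proposals change the divergence time but not the
// sizes, so each branch generator is eigendecomposed once per size value
// and exp(A t) columns are reconstructed per proposal:
//   P[, cols] = Re( V diag(exp(lambda t)) (V^-1 E_cols) ).
// The root functional w is cached per root-size value. Falls back to a
// dense matrix exponential when the eigenvector basis is ill-conditioned.

#include <RcppArmadillo.h>
#include "state_space.h"

arma::mat build_generator_cpp(int nmax, double coal_pair_rate, double u,
                              double v);
arma::vec root_functional_cpp(int nmax, double coal_pair_rate, double u,
                              double v);

struct BranchCache {
  double N = -1.0, u = -1.0, v = -1.0;
  int hits = 0;
  bool eig_ready = false, eig_failed = false;
  // the generator is block upper-triangular by lineage level and each
  // level block is a tridiagonal with positive sub/super products, so
  // the spectrum is real; stored as real factors
  arma::vec eval;
  arma::mat V;
  arma::mat VinvE;  // V^-1 restricted to the needed leaf states
  arma::mat A;         // generator (for the dense-exponential path)
  // candidate size value seen in recent proposals but not yet promoted
  // to the cached (eigendecomposed) value
  double cand_N = -1.0, cand_u = -1.0, cand_v = -1.0;
  int cand_hits = 0;
};

// memoized branch-top columns for recently seen (N, t) values
struct ColCache {
  double N = -1.0, u = -1.0, v = -1.0, t = -1.0;
  arma::mat C;
};

struct PairEngine {
  arma::imat pat;       // n1, r1, n2, r2, weight
  int n1max = 0, n2max = 0;
  arma::uvec cols1, cols2;    // needed state indices per side
  arma::uvec row_of, col_of;  // pattern row -> position in cols
  // per-pattern positions of its constant-state entries
  arma::uvec const_row_red, const_col_red, const_row_green, const_col_green;
  arma::mat LW;      // log-free hypergeometric pooling weights
  arma::umat IDXW;   // pooled state index per (state1, state2)
  BranchCache b1, b2;
  ColCache cc1[2], cc2[2];
  struct RootSlot {
    double Nr = -1.0, u = -1.0, v = -1.0;
    arma::mat W;
  };
  RootSlot root_slots[2];
  int root_mru = 0;
  const arma::mat* W = nullptr;
  int correction = 0;
  double total_weight = 0.0;
  int max_row = 0, max_col = 0;  // positions of (n1max, .) states

  void init(const arma::imat& patterns, int corr) {
    pat = patterns;
    correction = corr;
    n1max = pat.col(0).max();
    n2max = pat.col(2).max();
    int D1 = state_dim(n1max), D2 = state_dim(n2max);
    // collect needed states: observed plus constant states per n
    std::vector<int> need1(D1, 0), need2(D2, 0);
    for (arma::uword i = 0; i < pat.n_rows; ++i) {
      need1[state_index(pat(i, 0), pat(i, 1))] = 1;
      need2[state_index(pat(i, 2), pat(i, 3))] = 1;
      need1[state_index(pat(i, 0), 0)] = 1;
      need1[state_index(pat(i, 0), pat(i, 0))] = 1;
      need2[state_index(pat(i, 2), 0)] = 1;
      need2[state_index(pat(i, 2), pat(i, 2))] = 1;
      total_weight += pat(i, 4);
    }
    std::vector<int> pos1(D1, -1), pos2(D2, -1);
    std::vector<arma::uword> c1, c2;
    for (int s = 0; s < D1; ++s)
      if (need1[s]) { pos1[s] = c1.size(); c1.push_back(s); }
    for (int s = 0; s < D2; ++s)
      if (need2[s]) { pos2[s] = c2.size(); c2.push_back(s); }
    cols1 = arma::uvec(c1);
    cols2 = arma::uvec(c2);
    row_of.set_size(pat.n_rows);
    col_of.set_size(pat.n_rows);
    const_row_red.set_size(pat.n_rows);
    const_col_red.set_size(pat.n_rows);
    const_row_green.set_size(pat.n_rows);
    const_col_green.set_size(pat.n_rows);
    for (arma::uword i = 0; i < pat.n_rows; ++i) {
      row_of(i) = pos1[state_index(pat(i, 0), pat(i, 1))];
      col_of(i) = pos2[state_index(pat(i, 2), pat(i, 3))];
      const_row_red(i) = pos1[state_index(pat(i, 0), pat(i, 0))];
      const_col_red(i) = pos2[state_index(pat(i, 2), pat(i, 2))];
      const_row_green(i) = pos1[state_index(pat(i, 0), 0)];
      const_col_green(i) = pos2[state_index(pat(i, 2), 0)];
    }
    max_row = pos1[state_index(n1max, n1max)];
    max_col = pos2[state_index(n2max, n2max)];
    // pooling weights
    LW.set_size(D1, D2);
    IDXW.set_size(D1, D2);
    LW.zeros();
    for (int na = 0; na <= n1max; ++na)
      for (int ra = 0; ra <= na; ++ra)
        for (int nb = 0; nb <= n2max; ++nb)
          for (int rb = 0; rb <= nb; ++rb) {
            int i = state_index(na, ra), j = state_index(nb, rb);
            IDXW(i, j) = state_index(na + nb, ra + rb);
            LW(i, j) = std::exp(Rf_lchoose(na, ra) + Rf_lchoose(nb, rb) -
                                Rf_lchoose(na + nb, ra + rb));
          }
  }

  // exp(A t) E by uniformization: with L = max(-diag(A)) and
  // B = A + L I >= 0, exp(A t) = e^{-L t} exp(B t), expanded with Poisson
  // weights; stepped so each segment keeps L * dt moderate. All terms are
  // nonnegative, so the series has no cancellation. The generator is
  // applied through its triplet representation (a handful of entries per
  // state) into preallocated buffers.
  struct Scratch {
    std::vector<double> term, acc, tmp;
  };
  Scratch scratch;

  arma::mat uniform_cols(const arma::mat& A, double t,
                         const arma::uvec& cols) {
    int D = A.n_rows, m = cols.n_elem;
    arma::mat Y(D, m, arma::fill::zeros);
    for (int j = 0; j < m; ++j) Y(cols(j), j) = 1.0;
    if (t <= 0.0) return Y;
    double L = -A.diag().min() * 1.0000001 + 1e-12;
    // triplets of B = A + L I
    std::vector<int> Br, Bc;
    std::vector<double> Bv;
    Br.reserve(6 * D); Bc.reserve(6 * D); Bv.reserve(6 * D);
    for (int c = 0; c < D; ++c)
      for (int r = 0; r < D; ++r) {
        double val = A(r, c) + (r == c ? L : 0.0);
        if (val != 0.0) { Br.push_back(r); Bc.push_back(c); Bv.push_back(val); }
      }
    int nnz = Bv.size();
    int n_steps = (int)std::ceil(L * t / 40.0);
    if (n_steps < 1) n_steps = 1;
    double dt = t / n_steps;
    double a = L * dt;
    int mmax = (int)std::ceil(a + 8.0 * std::sqrt(a + 1.0) + 10.0);
    size_t sz = (size_t)D * m;
    scratch.term.assign(sz, 0.0);
    scratch.acc.assign(sz, 0.0);
    scratch.tmp.assign(sz, 0.0);
    double* term = scratch.term.data();
    double* acc = scratch.acc.data();
    double* tmp = scratch.tmp.data();
    double* y = Y.memptr();
    for (int s = 0; s < n_steps; ++s) {
      std::copy(y, y + sz, term);
      std::copy(y, y + sz, acc);
      for (int j = 1; j <= mmax; ++j) {
        double f = dt / j;
        std::fill(tmp, tmp + sz, 0.0);
        for (int e = 0; e < nnz; ++e) {
          const double v = Bv[e] * f;
          const double* src = term + Bc[e];
          double* dst = tmp + Br[e];
          for (int q = 0; q < m; ++q) dst[q * D] += v * src[q * D];
        }
        std::swap(term, tmp);
        double mx = 0.0;
        for (size_t q = 0; q < sz; ++q) {
          acc[q] += term[q];
          if (term[q] > mx) mx = term[q];
        }
        if (mx < 1e-18 && j > a) break;
      }
      double ea = std::exp(-a);
      for (size_t q = 0; q < sz; ++q) y[q] = acc[q] * ea;
    }
    return Y;
  }

  // Eigendecomposition exploiting the level structure: the generator is
  // block upper bidiagonal in the lineage count n, and each diagonal
  // block is a tridiagonal matrix with positive sub/super-diagonal
  // products, hence similar to a symmetric tridiagonal with a real
  // spectrum. Each eigenvector is seeded with a diagonal-block
  // eigenvector at its source level and extended to lower levels by
  // tridiagonal back-substitution. Orders of magnitude cheaper than a
  // dense nonsymmetric eigensolve.
  static bool build_eig_structured(BranchCache& bc, int nmax, double cr,
                                   double u, double v,
                                   const arma::uvec& cols) {
    int D = state_dim(nmax);
    arma::mat V(D, D, arma::fill::zeros);
    arma::vec ev(D, arma::fill::zeros);
    V(0, 0) = 1.0;
    int col = 1;
    std::vector<double> dm, sup, sub, Dsc, rhs, xprev, xn, tdiag, trhs;
    for (int m = 1; m <= nmax; ++m) {
      double cm2 = 0.5 * m * (m - 1) * cr;
      dm.assign(m + 1, 0.0); sup.assign(m + 1, 0.0); sub.assign(m + 1, 0.0);
      for (int r = 0; r <= m; ++r) {
        dm[r] = -(cm2 + r * u + (m - r) * v);
        if (r < m) sup[r] = (m - r) * v;
        if (r > 0) sub[r] = r * u;
      }
      arma::mat S(m + 1, m + 1, arma::fill::zeros);
      Dsc.assign(m + 1, 1.0);
      for (int r = 0; r <= m; ++r) S(r, r) = dm[r];
      for (int r = 0; r < m; ++r) {
        double s = std::sqrt(sup[r] * sub[r + 1]);
        S(r, r + 1) = s;
        S(r + 1, r) = s;
        Dsc[r + 1] = Dsc[r] * s / sup[r];
      }
      arma::vec la;
      arma::mat Wm;
      if (!arma::eig_sym(la, Wm, S)) return false;
      for (int j = 0; j <= m; ++j) {
        double lambda = la(j);
        // seed at level m
        std::vector<std::vector<double>> x(m + 1);
        x[m].resize(m + 1);
        for (int r = 0; r <= m; ++r) x[m][r] = Dsc[r] * Wm(r, j);
        // extend downward: (T_n - lambda) x_n = -C_{n,n+1} x_{n+1}
        bool ok = true;
        for (int n = m - 1; n >= 1 && ok; --n) {
          double cn2 = 0.5 * n * (n - 1) * cr;
          double cnp = 0.5 * (n + 1) * n * cr;
          tdiag.assign(n + 1, 0.0);
          trhs.assign(n + 1, 0.0);
          std::vector<double> tsup(n + 1, 0.0), tsub(n + 1, 0.0);
          for (int r = 0; r <= n; ++r) {
            tdiag[r] = -(cn2 + r * u + (n - r) * v) - lambda;
            if (r < n) tsup[r] = (n - r) * v;
            if (r > 0) tsub[r] = r * u;
            trhs[r] = -cnp * (((double)r / n) * x[n + 1][r + 1] +
                              ((double)(n - r) / n) * x[n + 1][r]);
          }
          // Thomas with a singularity guard
          double scale = cn2 + n * (u + v) + std::abs(lambda) + 1.0;
          for (int r = 1; r <= n; ++r) {
            if (std::abs(tdiag[r - 1]) < 1e-10 * scale) { ok = false; break; }
            double f = tsub[r] / tdiag[r - 1];
            tdiag[r] -= f * tsup[r - 1];
            trhs[r] -= f * trhs[r - 1];
          }
          if (!ok) break;
          if (std::abs(tdiag[n]) < 1e-10 * scale) { ok = false; break; }
          x[n].resize(n + 1);
          x[n][n] = trhs[n] / tdiag[n];
          for (int r = n - 1; r >= 0; --r)
            x[n][r] = (trhs[r] - tsup[r] * x[n][r + 1]) / tdiag[r];
        }
        if (!ok) return false;
        double mx = 0.0;
        for (int n = 1; n <= m; ++n)
          for (int r = 0; r <= n; ++r)
            mx = std::max(mx, std::abs(x[n][r]));
        if (mx <= 0.0 || !std::isfinite(mx)) return false;
        for (int n = 1; n <= m; ++n)
          for (int r = 0; r <= n; ++r)
            V(state_index(n, r), col) = x[n][r] / mx;
        ev(col) = lambda;
        ++col;
      }
    }
    arma::mat E(D, cols.n_elem, arma::fill::zeros);
    for (arma::uword j = 0; j < cols.n_elem; ++j) E(cols(j), j) = 1.0;
    arma::mat VinvE;
    if (!arma::solve(VinvE, V, E)) return false;
    if (arma::abs(V * VinvE - E).max() > 1e-8) return false;
    bc.eval = ev;
    bc.V = V;
    bc.VinvE = VinvE;
    bc.eig_ready = true;
    bc.eig_failed = false;
    return true;
  }

  static void build_eig(BranchCache& bc, const arma::uvec& cols) {
    bc.eig_failed = true;
    int nmax = 0;
    // recover nmax from the generator dimension
    while (state_dim(nmax + 1) <= (int)bc.A.n_rows) ++nmax;
    double cr = 1.0 / (2.0 * bc.N);
    if (build_eig_structured(bc, nmax, cr, bc.u, bc.v, cols)) return;
    // dense fallback for degenerate spectra
    arma::cx_vec eval;
    arma::cx_mat V;
    if (arma::eig_gen(eval, V, bc.A)) {
      double scale = arma::abs(eval).max() + 1e-300;
      if (arma::abs(arma::imag(eval)).max() > 1e-9 * scale) return;
      arma::mat Vr = arma::real(V);
      arma::mat E(bc.A.n_rows, cols.n_elem, arma::fill::zeros);
      for (arma::uword j = 0; j < cols.n_elem; ++j) E(cols(j), j) = 1.0;
      arma::mat VinvE;
      if (arma::solve(VinvE, Vr, E)) {
        arma::mat test = Vr * VinvE;
        if (arma::abs(test - E).max() < 1e-8) {
          bc.eval = arma::real(eval);
          bc.V = Vr;
          bc.VinvE = VinvE;
          bc.eig_ready = true;
          bc.eig_failed = false;
        }
      }
    }
  }

  // columns of exp(A t) at the needed leaf states; eigendecomposition is
  // built once a size value recurs (times vary over proposals; sizes are
  // sticky), otherwise a one-off dense exponential is cheaper
  arma::mat branch_cols(BranchCache& bc, ColCache* cc, int nmax, double N,
                        double u, double v, double t,
                        const arma::uvec& cols) {
    for (int s = 0; s < 2; ++s)
      if (cc[s].N == N && cc[s].u == u && cc[s].v == v && cc[s].t == t) {
        col_mru = s;
        return cc[s].C;
      }
    arma::mat C;
    if (bc.N != N || bc.u != u || bc.v != v) {
      bc.N = N; bc.u = u; bc.v = v;
      bc.eig_ready = false;
      bc.eig_failed = false;
      bc.A = build_generator_cpp(nmax, 1.0 / (2.0 * N), u, v);
    }
    if (!bc.eig_ready && !bc.eig_failed) build_eig(bc, cols);
    if (bc.eig_ready) {
      arma::mat S = bc.VinvE;
      arma::vec e = arma::exp(bc.eval * t);
      S.each_col() %= e;
      C = bc.V * S;
    } else {
      C = uniform_cols(bc.A, t, cols);
    }
    col_mru = 1 - col_mru;
    cc[col_mru] = {N, u, v, t, C};
    return C;
  }
  int col_mru = 0;

  void refresh_root(double Nr, double u, double v) {
    for (int s = 0; s < 2; ++s)
      if (root_slots[s].Nr == Nr && root_slots[s].u == u &&
          root_slots[s].v == v) {
        W = &root_slots[s].W;
        root_mru = s;
        return;
      }
    arma::vec w =
        root_functional_cpp(n1max + n2max, 1.0 / (2.0 * Nr), u, v);
    RootSlot& slot = root_slots[1 - root_mru];  // keep the MRU entry
    root_mru = 1 - root_mru;
    slot.Nr = Nr; slot.u = u; slot.v = v;
    slot.W.set_size(LW.n_rows, LW.n_cols);
    for (arma::uword i = 0; i < LW.n_rows; ++i)
      for (arma::uword j = 0; j < LW.n_cols; ++j)
        slot.W(i, j) = LW(i, j) * w(IDXW(i, j));
    W = &slot.W;
  }

  double loglik(double t, double Nr, double N1, double N2, double u,
                double v) {
    if (pat.n_rows == 0) return 0.0;
    refresh_root(Nr, u, v);
    arma::mat P1 = branch_cols(b1, cc1, n1max, N1, u, v, t, cols1);
    arma::mat P2 = branch_cols(b2, cc2, n2max, N2, u, v, t, cols2);
    arma::mat M = P1.t() * (*W) * P2;
    double ll = 0.0;
    for (arma::uword i = 0; i < pat.n_rows; ++i) {
      double p = M(row_of(i), col_of(i));
      if (correction == 1) {
        double pc = M(const_row_red(i), const_col_red(i)) +
                    M(const_row_green(i), const_col_green(i));
        p /= (1.0 - pc);
      }
      if (p <= 0.0 || !std::isfinite(p)) return -arma::datum::inf;
      ll += pat(i, 4) * std::log(p);
    }
    if (correction == 2) {
      // all-red and all-green at the maximum sample sizes; those states
      // are in cols because n1max/n2max are observed sample sizes
      double pc = M(max_row, max_col) + M(green_row(), green_col());
      double pv = 1.0 - pc;
      if (pv <= 0.0) return -arma::datum::inf;
      ll -= total_weight * std::log(pv);
    }
    return ll;
  }

  int max_green_row = -1, max_green_col = -1;
  int green_row() {
    if (max_green_row < 0)
      for (arma::uword j = 0; j < cols1.n_elem; ++j)
        if ((int)cols1(j) == state_index(n1max, 0)) max_green_row = j;
    return max_green_row;
  }
  int green_col() {
    if (max_green_col < 0)
      for (arma::uword j = 0; j < cols2.n_elem; ++j)
        if ((int)cols2(j) == state_index(n2max, 0)) max_green_col = j;
    return max_green_col;
  }
};

#endif
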
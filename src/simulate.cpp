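// Coalescent simulation of biallelic characters for one population pair.
// Gene trees follow the pair's species tree: independent coalescents in
// the two descendant populations truncated at the divergence time, with
// the survivors coalescing to a single ancestor in the root population.
// Characters evolve down the gene tree under the two-state CTMC, with
// the MRCA state drawn from stationarity. All sites of one locus share
// one gene tree (no intra-locus recombination); unlinked characters are
// loci of length one. Uses R's RNG so results are seed-reproducible.

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct Tree {
  // parent[i] > i for every non-root node; edge length = time[parent]-time
  std::vector<int> parent;
  std::vector<double> time;
  int root;
};

// one coalescent gene tree for n1 + n2 tips; tips 0..n1-1 from population
// 1, n1..n1+n2-1 from population 2
Tree simulate_tree(int n1, int n2, double t, double Nroot, double Nd1,
                   double Nd2) {
  int ntip = n1 + n2;
  Tree tr;
  tr.parent.assign(2 * ntip - 1, -1);
  tr.time.assign(2 * ntip - 1, 0.0);
  int next_node = ntip;
  std::vector<int> pool;

  auto coalesce = [&](std::vector<int>& act, double N, double start,
                      double stop) {
    double now = start;
    while ((int)act.size() > 1) {
      int k = act.size();
      double rate = 0.5 * k * (k - 1) / (2.0 * N);
      double wait = R::rexp(1.0 / rate);
      if (stop > 0 && now + wait > stop) break;
      now += wait;
      int i = (int)std::floor(R::runif(0.0, k));
      int j = (int)std::floor(R::runif(0.0, k - 1));
      if (j >= i) ++j;
      int a = act[i], b = act[j];
      int p = next_node++;
      tr.parent[a] = p;
      tr.parent[b] = p;
      tr.time[p] = now;
      if (i > j) std::swap(i, j);
      act.erase(act.begin() + j);
      act[i] = p;
    }
  };

  std::vector<int> act1, act2;
  for (int i = 0; i < n1; ++i) act1.push_back(i);
  for (int i = 0; i < n2; ++i) act2.push_back(n1 + i);
  if (n1 > 0) coalesce(act1, Nd1, 0.0, t);
  if (n2 > 0) coalesce(act2, Nd2, 0.0, t);
  pool = act1;
  pool.insert(pool.end(), act2.begin(), act2.end());
  coalesce(pool, Nroot, t, -1.0);
  tr.root = pool[0];
  tr.parent.resize(next_node);
  tr.time.resize(next_node);
  return tr;
}

}  // namespace

// Simulate pattern counts for one pair. Returns the (n1+1) x (n2+1)
// matrix of site counts by (r1, r2) plus the per-locus variable-site
// counts. n_loci gene trees, locus_len sites each.
// [[Rcpp::export]]
Rcpp::List sim_pair_counts_cpp(int n1, int n2, double t, double Nroot,
                               double Nd1, double Nd2, double u, double v,
                               int n_loci, int locus_len) {
  double pi_green = u / (u + v), pi_red = v / (u + v);
  arma::imat counts(n1 + 1, n2 + 1, arma::fill::zeros);
  IntegerVector locus_variable(n_loci);
  int ntip = n1 + n2;
  std::vector<int> state(2 * ntip - 1);
  std::vector<double> p_flip_red, p_flip_green;

  for (int l = 0; l < n_loci; ++l) {
    Tree tr = simulate_tree(n1, n2, t, Nroot, Nd1, Nd2);
    int nn = tr.parent.size();
    p_flip_red.assign(nn, 0.0);
    p_flip_green.assign(nn, 0.0);
    for (int i = 0; i < nn; ++i) {
      if (tr.parent[i] < 0) continue;
      double L = tr.time[tr.parent[i]] - tr.time[i];
      double decay = 1.0 - std::exp(-(u + v) * L);
      p_flip_red[i] = pi_green * decay;   // red -> green
      p_flip_green[i] = pi_red * decay;   // green -> red
    }
    int nvar = 0;
    for (int s = 0; s < locus_len; ++s) {
      state[tr.root] = (R::unif_rand() < pi_red) ? 1 : 0;
      for (int i = tr.root - 1; i >= 0; --i) {
        int ps = state[tr.parent[i]];
        double pf = ps == 1 ? p_flip_red[i] : p_flip_green[i];
        state[i] = (R::unif_rand() < pf) ? 1 - ps : ps;
      }
      int r1 = 0, r2 = 0;
      for (int i = 0; i < n1; ++i) r1 += state[i];
      for (int i = n1; i < ntip; ++i) r2 += state[i];
      counts(r1, r2) += 1;
      if (r1 + r2 > 0 && r1 + r2 < ntip) ++nvar;
    }
    locus_variable[l] = nvar;
  }
  return List::create(_["counts"] = counts,
                      _["locus_variable"] = locus_variable);
}

// Simulate a single gene tree, returned as parent pointers and node times
// (tips first, internal nodes in order of creation).
// [[Rcpp::export]]
Rcpp::List sim_gene_tree_cpp(int n1, int n2, double t, double Nroot,
                             double Nd1, double Nd2) {
  Tree tr = simulate_tree(n1, n2, t, Nroot, Nd1, Nd2);
  return List::create(_["parent"] = IntegerVector(tr.parent.begin(),
                                                  tr.parent.end()),
                      _["time"] = NumericVector(tr.time.begin(),
                                                tr.time.end()),
                      _["root"] = tr.root);
}
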
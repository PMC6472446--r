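// MCMC sampler for the joint posterior over divergence models (partition
// of pairs into divergence events plus event times) and per-pair nuisance
// parameters, under a Dirichlet-process prior on the partition.
//
// Operators per generation (one full sweep):
//   * multiplicative scale moves on each free per-pair size parameter,
//   * a window move on each free per-pair state frequency,
//   * a multiplicative scale move on each event time,
//   * a joint event-time / relative-root-size mixing move per event,
//   * one Gibbs sweep over pair-to-event assignments (Neal's Algorithm 8),
//   * an auxiliary-variable Gibbs update of the concentration parameter.
// All randomness comes from R's RNG.

#include <RcppArmadillo.h>
#include "state_space.h"
#include "pair_engine.h"
using namespace Rcpp;

namespace {

struct Config {
  double tau_shape, tau_rate;
  bool size_free;
  double size_shape, size_rate, size_fixed;
  bool rr_free;
  double rr_shape, rr_rate, rr_fixed;
  bool pi_free;
  double pi_a, pi_b, pi_fixed;
  bool alpha_free;
  double alpha_shape, alpha_rate, alpha_fixed;
  double mu;
  int correction;
  bool ignore_data;
  int n_aux;
  long generations;
  int sample_every;
  double win_size, win_tau, win_mixer, win_pi;
};

struct Chain {
  Config cfg;
  std::vector<arma::imat> pat;
  std::vector<PairEngine> eng;
  int np;
  std::vector<int> z;
  std::vector<double> tau;
  std::vector<double> Nd1, Nd2, Rr, pi_, uu, vv;
  double alpha;
  std::vector<double> ll;

  void set_uv(int i) {
    uu[i] = cfg.mu / (2.0 * (1.0 - pi_[i]));
    vv[i] = cfg.mu / (2.0 * pi_[i]);
  }
  double nroot(int i) const { return Rr[i] * 0.5 * (Nd1[i] + Nd2[i]); }

  double loglik_pair(int i, double tval) {
    if (cfg.ignore_data || pat[i].n_rows == 0) return 0.0;
    return eng[i].loglik(tval, Rr[i] * 0.5 * (Nd1[i] + Nd2[i]),
                         Nd1[i], Nd2[i], uu[i], vv[i]);
  }
  double loglik_pair_now(int i) { return loglik_pair(i, tau[z[i]]); }

  int k() const { return tau.size(); }

  std::vector<int> event_counts() const {
    std::vector<int> c(tau.size(), 0);
    for (int zi : z) c[zi]++;
    return c;
  }

  double log_prior() const {
    double lp = 0.0;
    std::vector<int> cnt = event_counts();
    lp += cnt.size() * std::log(alpha);
    for (int c : cnt) lp += std::lgamma((double)c);
    for (int i = 0; i < np; ++i) lp -= std::log(alpha + i);
    for (double tv : tau)
      lp += R::dgamma(tv, cfg.tau_shape, 1.0 / cfg.tau_rate, 1);
    for (int i = 0; i < np; ++i) {
      if (cfg.size_free) {
        lp += R::dgamma(Nd1[i], cfg.size_shape, 1.0 / cfg.size_rate, 1);
        lp += R::dgamma(Nd2[i], cfg.size_shape, 1.0 / cfg.size_rate, 1);
      }
      if (cfg.rr_free)
        lp += R::dgamma(Rr[i], cfg.rr_shape, 1.0 / cfg.rr_rate, 1);
      if (cfg.pi_free) lp += R::dbeta(pi_[i], cfg.pi_a, cfg.pi_b, 1);
    }
    if (cfg.alpha_free)
      lp += R::dgamma(alpha, cfg.alpha_shape, 1.0 / cfg.alpha_rate, 1);
    return lp;
  }

  void init_from_prior() {
    // Chinese restaurant process for the assignment, base distribution
    // draws for the event times, prior draws for nuisance parameters
    z.assign(np, 0);
    tau.clear();
    for (int i = 0; i < np; ++i) {
      double w = R::unif_rand() * (i + alpha);
      int e = -1;
      for (size_t j = 0; j < tau.size() && e < 0; ++j) {
        std::vector<int> cnt(tau.size(), 0);
        for (int q = 0; q < i; ++q) cnt[z[q]]++;
        if (w < cnt[j]) e = j; else w -= cnt[j];
      }
      if (e < 0) {
        tau.push_back(R::rgamma(cfg.tau_shape, 1.0 / cfg.tau_rate));
        e = tau.size() - 1;
      }
      z[i] = e;
    }
    for (int i = 0; i < np; ++i) {
      Nd1[i] = cfg.size_free ? R::rgamma(cfg.size_shape, 1.0 / cfg.size_rate)
                             : cfg.size_fixed;
      Nd2[i] = cfg.size_free ? R::rgamma(cfg.size_shape, 1.0 / cfg.size_rate)
                             : cfg.size_fixed;
      Rr[i] = cfg.rr_free ? R::rgamma(cfg.rr_shape, 1.0 / cfg.rr_rate)
                          : cfg.rr_fixed;
      pi_[i] = cfg.pi_free ? R::rbeta(cfg.pi_a, cfg.pi_b) : cfg.pi_fixed;
      set_uv(i);
    }
    for (int i = 0; i < np; ++i) ll[i] = loglik_pair_now(i);
  }

  void update_sizes() {
    for (int i = 0; i < np; ++i) {
      if (cfg.size_free) {
        for (int which = 0; which < 2; ++which) {
          std::vector<double>& Nd = which == 0 ? Nd1 : Nd2;
          double old = Nd[i];
          double s = std::exp(cfg.win_size * (R::unif_rand() - 0.5));
          Nd[i] = old * s;
          double lnew = loglik_pair_now(i);
          double lr = lnew - ll[i] + std::log(s) +
                      R::dgamma(Nd[i], cfg.size_shape, 1.0 / cfg.size_rate, 1) -
                      R::dgamma(old, cfg.size_shape, 1.0 / cfg.size_rate, 1);
          if (std::log(R::unif_rand()) < lr) ll[i] = lnew; else Nd[i] = old;
        }
      }
      if (cfg.rr_free) {
        double old = Rr[i];
        double s = std::exp(cfg.win_size * (R::unif_rand() - 0.5));
        Rr[i] = old * s;
        double lnew = loglik_pair_now(i);
        double lr = lnew - ll[i] + std::log(s) +
                    R::dgamma(Rr[i], cfg.rr_shape, 1.0 / cfg.rr_rate, 1) -
                    R::dgamma(old, cfg.rr_shape, 1.0 / cfg.rr_rate, 1);
        if (std::log(R::unif_rand()) < lr) ll[i] = lnew; else Rr[i] = old;
      }
      if (cfg.pi_free) {
        double old = pi_[i];
        double prop = old + cfg.win_pi * (R::unif_rand() - 0.5);
        while (prop <= 0.0 || prop >= 1.0) {
          if (prop <= 0.0) prop = -prop;
          if (prop >= 1.0) prop = 2.0 - prop;
        }
        pi_[i] = prop;
        set_uv(i);
        double lnew = loglik_pair_now(i);
        double lr = lnew - ll[i] + R::dbeta(prop, cfg.pi_a, cfg.pi_b, 1) -
                    R::dbeta(old, cfg.pi_a, cfg.pi_b, 1);
        if (std::log(R::unif_rand()) < lr) {
          ll[i] = lnew;
        } else {
          pi_[i] = old;
          set_uv(i);
        }
      }
    }
  }

  void update_times() {
    for (size_t e = 0; e < tau.size(); ++e) {
      double old = tau[e];
      double s = std::exp(cfg.win_tau * (R::unif_rand() - 0.5));
      double prop = old * s;
      double dll = 0.0;
      std::vector<std::pair<int, double>> lnew;
      for (int i = 0; i < np; ++i)
        if (z[i] == (int)e) {
          double l = loglik_pair(i, prop);
          lnew.push_back({i, l});
          dll += l - ll[i];
        }
      double lr = dll + std::log(s) +
                  R::dgamma(prop, cfg.tau_shape, 1.0 / cfg.tau_rate, 1) -
                  R::dgamma(old, cfg.tau_shape, 1.0 / cfg.tau_rate, 1);
      if (std::log(R::unif_rand()) < lr) {
        tau[e] = prop;
        for (auto& pr : lnew) ll[pr.first] = pr.second;
      }
    }
  }

  // Joint proposal along the divergence-time / root-size likelihood ridge:
  // scale the event time up while scaling the relative root sizes of its
  // pairs down (and vice versa).
  void update_mixer() {
    if (!cfg.rr_free) return;
    for (size_t e = 0; e < tau.size(); ++e) {
      double s = std::exp(cfg.win_mixer * (R::unif_rand() - 0.5));
      double tprop = tau[e] * s;
      std::vector<int> members;
      for (int i = 0; i < np; ++i)
        if (z[i] == (int)e) members.push_back(i);
      double lp_delta =
          R::dgamma(tprop, cfg.tau_shape, 1.0 / cfg.tau_rate, 1) -
          R::dgamma(tau[e], cfg.tau_shape, 1.0 / cfg.tau_rate, 1);
      std::vector<double> oldR(members.size());
      for (size_t m = 0; m < members.size(); ++m) {
        int i = members[m];
        oldR[m] = Rr[i];
        double rprop = Rr[i] / s;
        lp_delta += R::dgamma(rprop, cfg.rr_shape, 1.0 / cfg.rr_rate, 1) -
                    R::dgamma(Rr[i], cfg.rr_shape, 1.0 / cfg.rr_rate, 1);
        Rr[i] = rprop;
      }
      double dll = 0.0;
      std::vector<double> lnew(members.size());
      for (size_t m = 0; m < members.size(); ++m) {
        lnew[m] = loglik_pair(members[m], tprop);
        dll += lnew[m] - ll[members[m]];
      }
      double logJ = (1.0 - (double)members.size()) * std::log(s);
      double lr = dll + lp_delta + logJ;
      if (std::log(R::unif_rand()) < lr) {
        tau[e] = tprop;
        for (size_t m = 0; m < members.size(); ++m) ll[members[m]] = lnew[m];
      } else {
        for (size_t m = 0; m < members.size(); ++m) Rr[members[m]] = oldR[m];
      }
    }
  }

  void drop_empty_events() {
    std::vector<int> cnt = event_counts();
    std::vector<int> remap(tau.size(), -1);
    std::vector<double> tnew;
    for (size_t e = 0; e < tau.size(); ++e)
      if (cnt[e] > 0) {
        remap[e] = tnew.size();
        tnew.push_back(tau[e]);
      }
    for (int i = 0; i < np; ++i) z[i] = remap[z[i]];
    tau = tnew;
  }

  void update_partition() {
    for (int i = 0; i < np; ++i) {
      std::vector<int> cnt = event_counts();
      int old_e = z[i];
      cnt[old_e]--;
      bool singleton = cnt[old_e] == 0;
      int m = cfg.n_aux;
      std::vector<double> aux(m);
      if (singleton) {
        aux[0] = tau[old_e];
        for (int a = 1; a < m; ++a)
          aux[a] = R::rgamma(cfg.tau_shape, 1.0 / cfg.tau_rate);
      } else {
        for (int a = 0; a < m; ++a)
          aux[a] = R::rgamma(cfg.tau_shape, 1.0 / cfg.tau_rate);
      }
      int K = tau.size();
      std::vector<double> lw(K + m, -arma::datum::inf);
      std::vector<double> lcache(K + m);
      for (int e = 0; e < K; ++e) {
        if (cnt[e] == 0) continue;  // vacated event competes as auxiliary
        lcache[e] = cfg.ignore_data ? 0.0
                    : (e == old_e ? ll[i] : loglik_pair(i, tau[e]));
        lw[e] = std::log((double)cnt[e]) + lcache[e];
      }
      for (int a = 0; a < m; ++a) {
        lcache[K + a] = cfg.ignore_data ? 0.0 : loglik_pair(i, aux[a]);
        lw[K + a] = std::log(alpha / m) + lcache[K + a];
      }
      double mx = *std::max_element(lw.begin(), lw.end());
      double tot = 0.0;
      for (double& x : lw) {
        x = std::exp(x - mx);
        tot += x;
      }
      double udraw = R::unif_rand() * tot;
      int pick = 0;
      for (; pick < K + m - 1; ++pick) {
        if (udraw < lw[pick]) break;
        udraw -= lw[pick];
      }
      if (pick < K) {
        z[i] = pick;
      } else {
        tau.push_back(aux[pick - K]);
        z[i] = tau.size() - 1;
      }
      ll[i] = lcache[pick];
      drop_empty_events();
    }
  }

  void update_alpha() {
    if (!cfg.alpha_free) return;
    int kk = k();
    double a = cfg.alpha_shape, b = cfg.alpha_rate;
    double eta = R::rbeta(alpha + 1.0, (double)np);
    double odds = (a + kk - 1.0) / (np * (b - std::log(eta)));
    double shape = (R::unif_rand() < odds / (1.0 + odds)) ? a + kk
                                                          : a + kk - 1.0;
    alpha = R::rgamma(shape, 1.0 / (b - std::log(eta)));
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericMatrix run_chain_cpp(Rcpp::List pair_patterns,
                                  Rcpp::List config) {
  Chain ch;
  Config& c = ch.cfg;
  c.tau_shape = config["tau_shape"];
  c.tau_rate = config["tau_rate"];
  c.size_free = config["size_free"];
  c.size_shape = config["size_shape"];
  c.size_rate = config["size_rate"];
  c.size_fixed = config["size_fixed"];
  c.rr_free = config["rr_free"];
  c.rr_shape = config["rr_shape"];
  c.rr_rate = config["rr_rate"];
  c.rr_fixed = config["rr_fixed"];
  c.pi_free = config["pi_free"];
  c.pi_a = config["pi_a"];
  c.pi_b = config["pi_b"];
  c.pi_fixed = config["pi_fixed"];
  c.alpha_free = config["alpha_free"];
  c.alpha_shape = config["alpha_shape"];
  c.alpha_rate = config["alpha_rate"];
  c.alpha_fixed = config["alpha_fixed"];
  c.mu = config["mu"];
  c.correction = config["correction"];
  c.ignore_data = config["ignore_data"];
  c.n_aux = config["n_aux"];
  c.generations = (long)Rcpp::as<double>(config["generations"]);
  c.sample_every = config["sample_every"];
  c.win_size = config["win_size"];
  c.win_tau = config["win_tau"];
  c.win_mixer = config["win_mixer"];
  c.win_pi = config["win_pi"];

  ch.np = pair_patterns.size();
  for (int i = 0; i < ch.np; ++i) {
    ch.pat.push_back(Rcpp::as<arma::imat>(pair_patterns[i]));
    ch.eng.emplace_back();
    if (!c.ignore_data && ch.pat[i].n_rows > 0)
      ch.eng[i].init(ch.pat[i], c.correction);
  }
  ch.Nd1.assign(ch.np, 0.0);
  ch.Nd2.assign(ch.np, 0.0);
  ch.Rr.assign(ch.np, 0.0);
  ch.pi_.assign(ch.np, 0.5);
  ch.uu.assign(ch.np, 1.0);
  ch.vv.assign(ch.np, 1.0);
  ch.ll.assign(ch.np, 0.0);
  ch.alpha = c.alpha_free ? R::rgamma(c.alpha_shape, 1.0 / c.alpha_rate)
                          : c.alpha_fixed;
  ch.init_from_prior();
  for (int i = 0; i < ch.np; ++i)
    if (!std::isfinite(ch.ll[i]))
      Rcpp::stop("non-finite likelihood at initialization (pair %d)", i + 1);

  long n_samples = ch.cfg.generations / ch.cfg.sample_every + 1;
  int np = ch.np;
  int ncol = 5 + 7 * np;
  Rcpp::NumericMatrix out(n_samples, ncol);
  long row = 0;
  auto record = [&](long gen) {
    double lnl = 0.0;
    for (int i = 0; i < np; ++i) lnl += ch.ll[i];
    out(row, 0) = gen;
    out(row, 1) = lnl;
    out(row, 2) = ch.log_prior();
    out(row, 3) = ch.alpha;
    out(row, 4) = ch.k();
    for (int i = 0; i < np; ++i) {
      out(row, 5 + i) = ch.z[i];
      out(row, 5 + np + i) = ch.tau[ch.z[i]];
      out(row, 5 + 2 * np + i) = ch.Nd1[i];
      out(row, 5 + 3 * np + i) = ch.Nd2[i];
      out(row, 5 + 4 * np + i) = ch.nroot(i);
      out(row, 5 + 5 * np + i) = ch.Rr[i];
      out(row, 5 + 6 * np + i) = ch.pi_[i];
    }
    ++row;
  };
  record(0);
  for (long g = 1; g <= ch.cfg.generations; ++g) {
    ch.update_sizes();
    ch.update_times();
    ch.update_mixer();
    ch.update_partition();
    ch.update_alpha();
    if (g % ch.cfg.sample_every == 0) record(g);
    if (g % 1000 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
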
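// Adaptive random-walk Metropolis-within-Gibbs sampler for the
// state-space Ricker population models.
//
// Process (on pairs scale, latent state l_t = log N_t):
//   M0: l_t ~ N(l_{t-1} + beta0, sigma^2)
//   M1: l_t ~ N(l_{t-1} + beta0 + beta1 * N_{t-1}, sigma^2)
//   M2: l_t ~ N(l_{t-1} + beta0 + beta1 * N_{t-1} + beta2 * N_{t-2}, sigma^2)
// Observation:
//   pairs:       y_t ~ Poisson(N_t)
//   individuals: y_t ~ Poisson(K_t * N_t), K_t ~ N(m_kt, s_kt^2) trunc >= kmin
// Priors:
//   beta0 ~ U(b0lo, b0hi); beta1, beta2 ~ U(-10, 10); sigma ~ U(0, 2)
//   N_1 (and N_2 for M2) ~ U(n1lo, n1hi) on the natural scale.
//
// Missing counts contribute no observation term; their posterior-predictive
// draws are generated on the R side from the stored latent states.
//
// Uses R's RNG so chains are reproducible via set.seed() before each call.

#include <Rcpp.h>
using namespace Rcpp;

static inline double pois_ll(double y, double lambda) {
  // log Poisson pmf without the data-only constant would suffice for MCMC,
  // but the full value is stored for DIC, so keep lgamma(y+1).
  if (lambda <= 0.0) return R_NegInf;
  return y * std::log(lambda) - lambda - std::lgamma(y + 1.0);
}

struct Model {
  int kind;                 // 0, 1, 2
  int T;
  NumericVector y;          // counts, NA for missing
  LogicalVector obs;
  double b0lo, b0hi, b1lo, b1hi, b2lo, b2hi, siglo, sighi;
  double l1lo, l1hi;        // init-state prior bounds on log N
  bool has_k;
  NumericVector mk, sk;
  double kmin;
  int n_init;               // number of initial states with the uniform prior
  bool deterministic = false;  // sigma == 0: transitions have density 1

  // parameter state
  double beta0, beta1, beta2, sigma;
  std::vector<double> l;    // log N
  std::vector<double> K;

  int t0() const { return (kind == 2) ? 2 : 1; }  // first process index (0-based)

  double proc_mean(int t) const {
    // mean of l_t given predecessors (t is 0-based, t >= t0)
    double m = l[t - 1] + beta0;
    if (kind >= 1) m += beta1 * std::exp(l[t - 1]);
    if (kind == 2) m += beta2 * std::exp(l[t - 2]);
    return m;
  }

  double proc_term(int t) const {
    double m = proc_mean(t);
    double z = (l[t] - m) / sigma;
    return -0.5 * z * z - std::log(sigma);
  }

  double obs_term(int t) const {
    if (!obs[t]) return 0.0;
    double lambda = std::exp(l[t]);
    if (has_k) lambda *= K[t];
    return pois_ll(y[t], lambda);
  }

  double init_term(int t) const {
    // uniform prior on N in [exp(l1lo), exp(l1hi)] => density on l has
    // Jacobian e^l (up to the constant 1/(b-a), dropped).
    if (l[t] < l1lo || l[t] > l1hi) return R_NegInf;
    return l[t];
  }

  double k_prior(int t) const {
    if (K[t] < kmin) return R_NegInf;
    double z = (K[t] - mk[t]) / sk[t];
    return -0.5 * z * z;
  }

  // full log posterior (used by deterministic mode and for sanity)
  double log_post() const {
    double lp = 0.0;
    for (int t = 0; t < n_init; ++t) lp += init_term(t);
    if (!deterministic) for (int t = t0(); t < T; ++t) lp += proc_term(t);
    for (int t = 0; t < T; ++t) lp += obs_term(t);
    if (has_k) for (int t = 0; t < T; ++t) if (obs[t]) lp += k_prior(t);
    return lp;
  }

  double obs_loglik() const {
    double ll = 0.0;
    for (int t = 0; t < T; ++t) ll += obs_term(t);
    return ll;
  }
};

// log-posterior terms that involve l[t]
static double local_lp(const Model& M, int t) {
  double lp = M.obs_term(t);
  if (t < M.n_init) lp += M.init_term(t);
  if (t >= M.t0()) lp += M.proc_term(t);
  if (t + 1 < M.T && t + 1 >= M.t0()) lp += M.proc_term(t + 1);
  if (M.kind == 2 && t + 2 < M.T && t + 2 >= M.t0()) lp += M.proc_term(t + 2);
  return lp;
}

// log-posterior terms that involve the process parameters
static double proc_lp(const Model& M) {
  double lp = 0.0;
  for (int t = M.t0(); t < M.T; ++t) lp += M.proc_term(t);
  return lp;
}

struct Adapt {
  std::vector<double> step;
  std::vector<int> acc, n;
  int batch = 50, batch_idx = 0;
  explicit Adapt(int k, double s0) : step(k, s0), acc(k, 0), n(k, 0) {}
  void tally(int i, bool accepted) { n[i]++; if (accepted) acc[i]++; }
  void maybe_adapt() {
    if (n.empty() || n[0] < batch) return;
    batch_idx++;
    double delta = std::min(0.1, 1.0 / std::sqrt((double)batch_idx));
    for (size_t i = 0; i < step.size(); ++i) {
      double rate = n[i] > 0 ? (double)acc[i] / n[i] : 0.44;
      step[i] *= std::exp(rate > 0.44 ? delta : -delta);
      acc[i] = 0; n[i] = 0;
    }
  }
};

// [[Rcpp::export]]
List ssm_chain(NumericVector y, LogicalVector obs, int kind,
               NumericVector b0_bounds, NumericVector b1_bounds,
               NumericVector b2_bounds, NumericVector sig_bounds,
               NumericVector l1_bounds, int n_init,
               bool has_k, NumericVector mk, NumericVector sk, double kmin,
               double sigma_fixed,   // < 0: estimate; >= 0: fixed
               bool l1_only,         // deterministic states (sigma == 0)
               int n_iter, int n_burn, int thin,
               NumericVector init_par, NumericVector init_l,
               NumericVector init_K) {
  Model M;
  M.kind = kind; M.T = y.size(); M.y = y; M.obs = obs;
  M.b0lo = b0_bounds[0]; M.b0hi = b0_bounds[1];
  M.b1lo = b1_bounds[0]; M.b1hi = b1_bounds[1];
  M.b2lo = b2_bounds[0]; M.b2hi = b2_bounds[1];
  M.siglo = sig_bounds[0]; M.sighi = sig_bounds[1];
  M.l1lo = l1_bounds[0]; M.l1hi = l1_bounds[1];
  M.n_init = n_init;
  M.has_k = has_k; M.mk = mk; M.sk = sk; M.kmin = kmin;

  M.beta0 = init_par[0]; M.beta1 = init_par[1]; M.beta2 = init_par[2];
  M.sigma = (sigma_fixed >= 0) ? sigma_fixed : init_par[3];
  M.deterministic = l1_only;
  M.l.assign(init_l.begin(), init_l.end());
  M.K.assign(init_K.begin(), init_K.end());

  bool est_sigma = sigma_fixed < 0;
  int npar = 5;               // beta0, beta1, beta2, sigma, joint-ridge slots
  Adapt ad_par(npar, 0.1), ad_l(M.T, 0.2), ad_k(has_k ? M.T : 0, 0.05);
  ad_par.step[4] = 1e-4;      // joint (beta0, beta1) move, beta1 scale
  // typical abundance scale, for the (beta0, beta1) ridge direction
  double Nbar = 0.0; int nobs = 0;
  for (int t = 0; t < M.T; ++t) if (obs[t]) { Nbar += y[t]; nobs++; }
  Nbar = nobs > 0 ? Nbar / nobs : 1.0;
  if (has_k) {
    double mkbar = 0.0; int nk = 0;
    for (int t = 0; t < M.T; ++t) if (obs[t]) { mkbar += mk[t]; nk++; }
    if (nk > 0 && mkbar > 0) Nbar /= (mkbar / nk);  // back to pairs scale
  }

  int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix out_par(n_keep, 4);
  NumericMatrix out_l(n_keep, M.T);
  NumericMatrix out_k(has_k ? n_keep : 0, has_k ? M.T : 0);
  NumericVector out_ll(n_keep);

  RNGScope scope;

  auto propagate = [&](void) {
    // deterministic trajectory from the initial state(s) (sigma == 0 mode)
    for (int t = M.t0(); t < M.T; ++t) M.l[t] = M.proc_mean(t);
  };
  if (l1_only) propagate();

  double cur_lp = l1_only ? M.log_post() : 0.0;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    if (l1_only) {
      // joint updates of (initial states, betas): trajectory recomputed
      for (int t = 0; t < M.n_init; ++t) {
        double old = M.l[t];
        M.l[t] = old + norm_rand() * ad_l.step[t];
        propagate();
        double new_lp = M.log_post();
        bool acc = std::log(unif_rand()) < new_lp - cur_lp;
        if (acc) cur_lp = new_lp; else { M.l[t] = old; propagate(); }
        if (it < n_burn) ad_l.tally(t, acc);
      }
      double* pars[3] = { &M.beta0, &M.beta1, &M.beta2 };
      double lo[3] = { M.b0lo, M.b1lo, M.b2lo };
      double hi[3] = { M.b0hi, M.b1hi, M.b2hi };
      int np = (kind == 0) ? 1 : (kind == 1 ? 2 : 3);
      for (int p = 0; p < np; ++p) {
        double old = *pars[p];
        double prop = old + norm_rand() * ad_par.step[p];
        bool acc = false;
        if (prop >= lo[p] && prop <= hi[p]) {
          *pars[p] = prop;
          propagate();
          double new_lp = M.log_post();
          acc = std::log(unif_rand()) < new_lp - cur_lp;
          if (acc) cur_lp = new_lp; else { *pars[p] = old; propagate(); }
        }
        if (it < n_burn) ad_par.tally(p, acc);
      }
      if (it < n_burn) { ad_l.maybe_adapt(); ad_par.maybe_adapt(); }
    } else {
      // latent states
      for (int t = 0; t < M.T; ++t) {
        double old = M.l[t];
        double lp0 = local_lp(M, t);
        M.l[t] = old + norm_rand() * ad_l.step[t];
        double lp1 = local_lp(M, t);
        bool acc = std::log(unif_rand()) < lp1 - lp0;
        if (!acc) M.l[t] = old;
        if (it < n_burn) ad_l.tally(t, acc);
      }
      // betas
      double* pars[3] = { &M.beta0, &M.beta1, &M.beta2 };
      double lo[3] = { M.b0lo, M.b1lo, M.b2lo };
      double hi[3] = { M.b0hi, M.b1hi, M.b2hi };
      int np = (kind == 0) ? 1 : (kind == 1 ? 2 : 3);
      for (int p = 0; p < np; ++p) {
        double old = *pars[p];
        double lp0 = proc_lp(M);
        double prop = old + norm_rand() * ad_par.step[p];
        bool acc = false;
        if (prop >= lo[p] && prop <= hi[p]) {
          *pars[p] = prop;
          double lp1 = proc_lp(M);
          acc = std::log(unif_rand()) < lp1 - lp0;
          if (!acc) *pars[p] = old;
        }
        if (it < n_burn) ad_par.tally(p, acc);
      }
      // joint ridge move: beta1 and beta0 are strongly negatively
      // correlated (beta0 ~ -beta1 * N at equilibrium); propose along the
      // ridge so the pair mixes
      if (kind >= 1) {
        double d = norm_rand() * ad_par.step[4];
        double b1p = M.beta1 + d, b0p = M.beta0 - d * Nbar;
        bool acc = false;
        if (b1p >= M.b1lo && b1p <= M.b1hi &&
            b0p >= M.b0lo && b0p <= M.b0hi) {
          double lp0 = proc_lp(M);
          double ob0 = M.beta0, ob1 = M.beta1;
          M.beta0 = b0p; M.beta1 = b1p;
          double lp1 = proc_lp(M);
          acc = std::log(unif_rand()) < lp1 - lp0;
          if (!acc) { M.beta0 = ob0; M.beta1 = ob1; }
        }
        if (it < n_burn) ad_par.tally(4, acc);
      }
      // sigma
      if (est_sigma) {
        double old = M.sigma;
        double lp0 = proc_lp(M);
        double prop = old + norm_rand() * ad_par.step[3];
        bool acc = false;
        if (prop > M.siglo && prop < M.sighi) {
          M.sigma = prop;
          double lp1 = proc_lp(M);
          acc = std::log(unif_rand()) < lp1 - lp0;
          if (!acc) M.sigma = old;
        }
        if (it < n_burn) ad_par.tally(3, acc);
      }
      // conversion factors
      if (has_k) {
        for (int t = 0; t < M.T; ++t) {
          if (!M.obs[t]) continue;    // K only enters through the obs term
          double old = M.K[t];
          double lp0 = M.k_prior(t) + M.obs_term(t);
          M.K[t] = old + norm_rand() * ad_k.step[t];
          double lp1 = M.k_prior(t) + M.obs_term(t);
          bool acc = std::log(unif_rand()) < lp1 - lp0;
          if (!acc) M.K[t] = old;
          if (it < n_burn) ad_k.tally(t, acc);
        }
      }
      if (it < n_burn) {
        ad_l.maybe_adapt(); ad_par.maybe_adapt();
        if (has_k) ad_k.maybe_adapt();
      }
    }

    if (it >= n_burn && (it - n_burn) % thin == 0 && kept < n_keep) {
      out_par(kept, 0) = M.beta0; out_par(kept, 1) = M.beta1;
      out_par(kept, 2) = M.beta2; out_par(kept, 3) = M.sigma;
      for (int t = 0; t < M.T; ++t) out_l(kept, t) = std::exp(M.l[t]);
      if (has_k) for (int t = 0; t < M.T; ++t) out_k(kept, t) = M.K[t];
      out_ll[kept] = M.obs_loglik();
      kept++;
    }
  }

  return List::create(_["params"] = out_par, _["N"] = out_l,
                      _["K"] = out_k, _["loglik"] = out_ll,
                      _["step_l"] = NumericVector(ad_l.step.begin(),
                                                  ad_l.step.end()),
                      _["step_par"] = NumericVector(ad_par.step.begin(),
                                                    ad_par.step.end()));
}
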
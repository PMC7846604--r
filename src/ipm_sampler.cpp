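// Metropolis-within-Gibbs sampler for the manatee integrated population
// model. The target density combines (a) priors on link-scale vital
// rates, mortality ratios, recovery parameters, and the initial census,
// (b) the binomial stage-projection process, and (c) carcass-recovery,
// abundance-survey, and synoptic lower-bound likelihoods.
//
// Layout conventions shared with the R side (see R/ipm_inference.R):
//   stages   0 f2, 1 f3, 2 f4, 3 p, 4 c, 5 b, 6 m2, 7 m3, 8 m4, 9 ma
//   latents  0 S1, 1 Sf4, 2 Sp, 3 Sc, 4 Sb, 5 Sm4, 6 Sma,
//            7 G4, 8 Gp, 9 Gb, 10 Nf2', 11 Nf3', 12 Nf4', 13 Nm3', 14 Nm4'
// All random numbers come from R's RNG so set.seed() on the R side makes
// runs reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <functional>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// binomial log-pmf, -Inf outside the support, point masses at p = 0, 1
static inline double lbinom(double x, double n, double p) {
  if (n < 0.0 || x < 0.0 || x > n) return NEG_INF;
  if (p <= 0.0) return (p == 0.0 && x == 0.0) ? 0.0 : NEG_INF;
  if (p >= 1.0) return (p == 1.0 && x == n) ? 0.0 : NEG_INF;
  return R::dbinom(x, n, p, 1);
}

static inline double plogis_(double x) { return 1.0 / (1.0 + std::exp(-x)); }
static inline double clip01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

struct Rates { double s1, s2, s3, s4, sp, sa, g4, gp, gb; };

class IpmModel {
public:
  int T, T1;                       // census years; transitions = T - 1
  NumericVector sa_mu, sa_sd, gb_mu, gb_sd;
  double g4_mu, g4_sd;
  NumericVector rho_mu, rho_sd;    // 4, lognormal (normal on log rho)
  double a_mu, a_sd, sig_scale;
  double init_mu, init_sd;
  NumericVector dir_alpha;         // 10
  IntegerMatrix C;                 // 3 x T1; first row -1 => no data
  IntegerVector surv_idx;          // 0-based census-year indices
  NumericVector surv_mu, surv_sd;
  NumericVector syn_bound;         // length T; <= 0 => no bound
  double r_fixed;                  // < 0 => estimate recovery params

  // parameter vector offsets
  int off_lsa, off_lgb, off_lg4, off_lrho, off_a, off_eps, off_lsig,
      off_lN0, off_w, n_par;

  std::vector<double> par;
  std::vector<int> L;              // 15 x T1, column-major
  std::vector<int> n;              // 10 x T, column-major

  explicit IpmModel(List data) {
    T = as<int>(data["T"]);
    T1 = T - 1;
    sa_mu = data["sa_mu"]; sa_sd = data["sa_sd"];
    gb_mu = data["gb_mu"]; gb_sd = data["gb_sd"];
    g4_mu = as<double>(data["g4_mu"]); g4_sd = as<double>(data["g4_sd"]);
    rho_mu = data["rho_mu"]; rho_sd = data["rho_sd"];
    a_mu = as<double>(data["a_mu"]); a_sd = as<double>(data["a_sd"]);
    sig_scale = as<double>(data["sig_scale"]);
    init_mu = as<double>(data["init_mu"]);
    init_sd = as<double>(data["init_sd"]);
    dir_alpha = data["dir_alpha"];
    C = as<IntegerMatrix>(data["C"]);
    surv_idx = data["surv_idx"];
    surv_mu = data["surv_mu"]; surv_sd = data["surv_sd"];
    syn_bound = data["syn_bound"];
    r_fixed = as<double>(data["r_fixed"]);
    off_lsa = 0;
    off_lgb = T1;
    off_lg4 = 2 * T1;
    off_lrho = 2 * T1 + 1;
    off_a = 2 * T1 + 5;
    off_eps = 2 * T1 + 8;
    off_lsig = 3 * T1 + 8;
    off_lN0 = 3 * T1 + 9;
    off_w = 3 * T1 + 10;
    n_par = 3 * T1 + 20;
    L.assign(15 * T1, 0);
    n.assign(10 * T, 0);
  }

  inline int& Lat(int r, int t) { return L[r + 15 * t]; }
  inline int& N(int s, int y) { return n[s + 10 * y]; }
  inline double Ntot(int y) {
    double tot = 0.0;
    for (int s = 0; s < 10; ++s) tot += N(s, y);
    return tot + N(4, y);
  }

  Rates rates(int t) const {
    Rates rt;
    rt.sa = plogis_(par[off_lsa + t]);
    double qa = 1.0 - rt.sa;
    rt.s1 = clip01(1.0 - std::exp(par[off_lrho + 0]) * qa);
    rt.s2 = clip01(1.0 - std::exp(par[off_lrho + 1]) * qa);
    rt.s3 = clip01(1.0 - std::exp(par[off_lrho + 2]) * qa);
    rt.s4 = clip01(1.0 - std::exp(par[off_lrho + 3]) * qa);
    rt.sp = rt.sa;
    rt.gb = plogis_(par[off_lgb + t]);
    rt.gp = rt.gb;
    rt.g4 = plogis_(par[off_lg4]);
    return rt;
  }

  // deterministic largest-remainder allocation of the initial census;
  // must match allocate_counts() on the R side exactly
  void set_initial_state() {
    double g[10], sum = 0.0;
    for (int i = 0; i < 10; ++i) { g[i] = std::exp(par[off_w + i]); sum += g[i]; }
    double p[10];
    for (int i = 0; i < 10; ++i) p[i] = g[i] / sum;
    double N0 = std::exp(par[off_lN0]);
    double S = N0 / (1.0 + p[4]);
    double target[10], frac[10];
    int base[10]; double bsum = 0.0;
    for (int i = 0; i < 10; ++i) {
      target[i] = S * p[i];
      base[i] = (int)std::floor(target[i]);
      frac[i] = target[i] - base[i];
      bsum += base[i];
    }
    int rem = (int)(std::nearbyint(S) - bsum);
    if (rem > 0) {
      int idx[10];
      for (int i = 0; i < 10; ++i) idx[i] = i;
      std::stable_sort(idx, idx + 10,
                       [&](int a, int b) { return frac[a] > frac[b]; });
      for (int k = 0; k < rem && k < 10; ++k) base[idx[k]] += 1;
    }
    for (int i = 0; i < 10; ++i) N(i, 0) = base[i];
  }

  // recompute census t+1 from latents of transition t
  void set_next_state(int t) {
    int y = t + 1;
    N(0, y) = Lat(10, t);
    N(1, y) = Lat(11, t);
    N(2, y) = Lat(12, t);
    N(3, y) = (Lat(1, t) - Lat(7, t)) + (Lat(2, t) - Lat(8, t));
    N(4, y) = Lat(7, t) + Lat(8, t) + Lat(9, t);
    N(5, y) = Lat(3, t) + (Lat(4, t) - Lat(9, t));
    N(6, y) = Lat(0, t) - Lat(10, t);
    N(7, y) = Lat(13, t);
    N(8, y) = Lat(14, t);
    N(9, y) = Lat(5, t) + Lat(6, t);
  }

  void rebuild_states() {
    set_initial_state();
    for (int t = 0; t < T1; ++t) set_next_state(t);
  }

  double proc_lp(int t) {
    Rates rt = rates(t);
    double lp = 0.0;
    lp += lbinom(Lat(0, t), N(4, t), rt.s1);
    lp += lbinom(Lat(1, t), N(2, t), rt.s4);
    lp += lbinom(Lat(2, t), N(3, t), rt.sp);
    lp += lbinom(Lat(3, t), N(4, t), rt.sa);
    lp += lbinom(Lat(4, t), N(5, t), rt.sa);
    lp += lbinom(Lat(5, t), N(8, t), rt.s4);
    lp += lbinom(Lat(6, t), N(9, t), rt.sa);
    lp += lbinom(Lat(7, t), Lat(1, t), rt.g4);
    lp += lbinom(Lat(8, t), Lat(2, t), rt.gp);
    lp += lbinom(Lat(9, t), Lat(4, t), rt.gb);
    lp += lbinom(Lat(10, t), Lat(0, t), 0.5);
    lp += lbinom(Lat(11, t), N(0, t), rt.s2);
    lp += lbinom(Lat(12, t), N(1, t), rt.s3);
    lp += lbinom(Lat(13, t), N(6, t), rt.s2);
    lp += lbinom(Lat(14, t), N(7, t), rt.s3);
    return lp;
  }

  void deaths(int t, double M[3]) {
    M[0] = (N(4, t) - Lat(0, t)) + (N(0, t) - Lat(11, t)) +
           (N(6, t) - Lat(13, t));
    M[1] = (N(1, t) - Lat(12, t)) + (N(7, t) - Lat(14, t)) +
           (N(2, t) - Lat(1, t)) + (N(8, t) - Lat(5, t));
    M[2] = (N(3, t) - Lat(2, t)) + (N(4, t) - Lat(3, t)) +
           (N(5, t) - Lat(4, t)) + (N(9, t) - Lat(6, t));
  }

  inline double recov(int s, int t) {
    if (r_fixed >= 0.0) return r_fixed;
    return plogis_(par[off_a + s] + par[off_eps + t]);
  }

  double carc_lp(int t) {
    if (C(0, t) < 0) return 0.0;
    double M[3];
    deaths(t, M);
    double lp = 0.0;
    for (int s = 0; s < 3; ++s) lp += lbinom(C(s, t), M[s], recov(s, t));
    return lp;
  }

  double year_data_lp(int y) {
    double lp = 0.0;
    double tot = Ntot(y);
    for (int j = 0; j < surv_idx.size(); ++j) {
      if (surv_idx[j] == y) {
        if (tot <= 0.0) return NEG_INF;
        lp += R::dlnorm(tot, surv_mu[j], surv_sd[j], 1);
      }
    }
    if (syn_bound[y] > 0.0 && tot < syn_bound[y]) return NEG_INF;
    return lp;
  }

  double prior_lp() {
    double lp = 0.0;
    for (int t = 0; t < T1; ++t) {
      lp += R::dnorm(par[off_lsa + t], sa_mu[t], sa_sd[t], 1);
      lp += R::dnorm(par[off_lgb + t], gb_mu[t], gb_sd[t], 1);
    }
    lp += R::dnorm(par[off_lg4], g4_mu, g4_sd, 1);
    for (int k = 0; k < 4; ++k)
      lp += R::dnorm(par[off_lrho + k], rho_mu[k], rho_sd[k], 1);
    for (int s = 0; s < 3; ++s)
      lp += R::dnorm(par[off_a + s], a_mu, a_sd, 1);
    double sigma = std::exp(par[off_lsig]);
    for (int t = 0; t < T1; ++t)
      lp += R::dnorm(par[off_eps + t], 0.0, sigma, 1);
    // half-normal hyperprior on sigma, with Jacobian of the log transform
    lp += M_LN2 + R::dnorm(sigma, 0.0, sig_scale, 1) + par[off_lsig];
    lp += R::dnorm(par[off_lN0], init_mu, init_sd, 1);
    // gamma representation of the Dirichlet structure prior (log scale)
    for (int i = 0; i < 10; ++i) {
      double a = dir_alpha[i], w = par[off_w + i];
      lp += a * w - std::exp(w) - std::lgamma(a);
    }
    return lp;
  }

  double total_lp() {
    double lp = prior_lp();
    for (int t = 0; t < T1; ++t) lp += proc_lp(t) + carc_lp(t);
    for (int y = 0; y < T; ++y) lp += year_data_lp(y);
    return lp;
  }

  // terms touched downstream when census t+1 changes
  double downstream_lp(int t) {
    double lp = year_data_lp(t + 1);
    if (t + 1 < T1) lp += proc_lp(t + 1) + carc_lp(t + 1);
    return lp;
  }

  // terms touched by a survivor-chain shift starting at transition t0:
  // the shift changes deaths only in year t0 (later increments cancel
  // in the death bookkeeping), so one carcass term, the process terms
  // from t0 on, and the abundance/synoptic terms of later years
  double chain_local_lp(int t0) {
    double lp = carc_lp(t0);
    for (int t = t0; t < T1; ++t) lp += proc_lp(t);
    for (int y = t0 + 1; y < T; ++y) lp += year_data_lp(y);
    return lp;
  }

  // everything a from-t0 cohort move can touch (carcass terms included
  // defensively; a death-neutral move cancels them exactly)
  double cohort_local_lp(int t0) {
    double lp = 0.0;
    for (int t = t0; t < T1; ++t) lp += proc_lp(t) + carc_lp(t);
    for (int y = t0 + 1; y < T; ++y) lp += year_data_lp(y);
    return lp;
  }

  // add or remove k births at transition t0 and carry the change
  // through: the new mothers-with-calf pairs, the breeder chain the
  // mothers rejoin, and the male half of the calf cohort as it ages
  // into the adult-male chain; no death tally changes anywhere
  void shift_births(int t0, int k) {
    Lat(9, t0) += k;                                   // Gb
    if (t0 + 1 < T1) { Lat(0, t0 + 1) += k; Lat(3, t0 + 1) += k; }
    for (int t = t0 + 2; t < T1; ++t) Lat(4, t) += k;  // Sb chain
    if (t0 + 2 < T1) Lat(13, t0 + 2) += k;             // Nm3'
    if (t0 + 3 < T1) Lat(14, t0 + 3) += k;             // Nm4'
    if (t0 + 4 < T1) Lat(5, t0 + 4) += k;              // Sm4
    for (int t = t0 + 5; t < T1; ++t) Lat(6, t) += k;  // Sma chain
    for (int t = t0; t < T1; ++t) set_next_state(t);
  }
};

// ---------------------------------------------------------------------------

static void copy_par_lat(IpmModel& m, NumericVector par_init,
                         IntegerMatrix lat_init) {
  if ((int)par_init.size() != m.n_par)
    stop("parameter vector has length %d, expected %d",
         (int)par_init.size(), m.n_par);
  if (lat_init.nrow() != 15 || lat_init.ncol() != m.T1)
    stop("latent matrix must be 15 x (T - 1)");
  m.par.assign(par_init.begin(), par_init.end());
  for (int t = 0; t < m.T1; ++t)
    for (int r = 0; r < 15; ++r) m.Lat(r, t) = lat_init(r, t);
  m.rebuild_states();
}

// [[Rcpp::export]]
double ipm_logpost_cpp(List data, NumericVector par, IntegerMatrix lat) {
  IpmModel m(data);
  copy_par_lat(m, par, lat);
  return m.total_lp();
}

// [[Rcpp::export]]
IntegerVector allocate_counts_cpp(double N0, NumericVector p10) {
  // exposed for parity tests against the R implementation
  List data = List::create(
    _["T"] = 2, _["sa_mu"] = NumericVector(1), _["sa_sd"] = NumericVector(1, 1.0),
    _["gb_mu"] = NumericVector(1), _["gb_sd"] = NumericVector(1, 1.0),
    _["g4_mu"] = 0.0, _["g4_sd"] = 1.0,
    _["rho_mu"] = NumericVector(4), _["rho_sd"] = NumericVector(4, 1.0),
    _["a_mu"] = 0.0, _["a_sd"] = 1.0, _["sig_scale"] = 1.0,
    _["init_mu"] = 0.0, _["init_sd"] = 1.0,
    _["dir_alpha"] = NumericVector(10, 1.0),
    _["C"] = IntegerMatrix(3, 1),
    _["surv_idx"] = IntegerVector(0), _["surv_mu"] = NumericVector(0),
    _["surv_sd"] = NumericVector(0), _["syn_bound"] = NumericVector(2),
    _["r_fixed"] = -1.0);
  IpmModel m(data);
  m.par.assign(m.n_par, 0.0);
  double tot = 0.0;
  for (int i = 0; i < 10; ++i) tot += p10[i];
  m.par[m.off_lN0] = std::log(N0);
  for (int i = 0; i < 10; ++i) m.par[m.off_w + i] = std::log(p10[i] / tot);
  m.set_initial_state();
  IntegerVector out(10);
  for (int i = 0; i < 10; ++i) out[i] = m.N(i, 0);
  return out;
}

// [[Rcpp::export]]
List ipm_mcmc_cpp(List data, NumericVector par_init, IntegerMatrix lat_init,
                  List settings) {
  IpmModel m(data);
  copy_par_lat(m, par_init, lat_init);

  const int n_iter = as<int>(settings["n_iter"]);
  const int n_burn = as<int>(settings["n_burnin"]);
  const int thin = as<int>(settings["thin"]);
  const bool est_r = m.r_fixed < 0.0;
  const int T1 = m.T1, T = m.T;

  // proposal scales for continuous parameters, adapted during burn-in
  std::vector<double> scale(m.n_par, 0.2);
  for (int t = 0; t < T1; ++t) {
    scale[m.off_lsa + t] = std::max(0.02, 1.5 * m.sa_sd[t]);
    scale[m.off_lgb + t] = std::max(0.02, 1.5 * m.gb_sd[t]);
  }
  scale[m.off_lg4] = 1.0;
  for (int k = 0; k < 4; ++k) scale[m.off_lrho + k] = 0.15;
  scale[m.off_lN0] = 0.05;
  for (int i = 0; i < 10; ++i) scale[m.off_w + i] = 0.3;
  std::vector<double> acc(m.n_par, 0.0), trials(m.n_par, 0.0);
  double lat_acc = 0.0, lat_try = 0.0, blk_acc = 0.0, blk_try = 0.0;
  double level_acc = 0.0, level_try = 0.0, level_scale = 0.02;
  // adaptive magnitudes for the joint integer moves (frozen after burn-in)
  double birth_k = 2.0, birth_acc = 0.0, birth_try = 0.0;
  double chain_k = 3.0, chain_acc = 0.0, chain_try = 0.0;

  const int n_keep = (n_iter > n_burn) ? (n_iter - n_burn) / thin : 0;
  const int n_col = 8 * T1 + 11 * T + 10;
  NumericMatrix out(n_keep, n_col);
  int row = 0;

  // generic scalar Metropolis step on par[j]; delta_fn returns the local
  // log-posterior for the current parameter value
  auto mh_scalar = [&](int j, std::function<double()> local_lp,
                       std::function<void()> on_change) {
    double cur = local_lp();
    double old = m.par[j];
    m.par[j] = old + R::norm_rand() * scale[j];
    on_change();
    double prop = local_lp();
    trials[j] += 1.0;
    if (std::log(R::unif_rand()) < prop - cur) {
      acc[j] += 1.0;
    } else {
      m.par[j] = old;
      on_change();
    }
  };
  auto noop = [&]() {};
  auto refresh_init = [&]() { m.set_initial_state(); };

  for (int iter = 1; iter <= n_iter; ++iter) {
    // -- latent integer random-walk updates ------------------------------
    // the local density is the same function for all 15 rows of a
    // transition, so it is computed once and carried across proposals
    for (int t = 0; t < T1; ++t) {
      double cur = m.proc_lp(t) + m.carc_lp(t) + m.downstream_lp(t);
      for (int r = 0; r < 15; ++r) {
        int old = m.Lat(r, t);
        int step = 1 + (int)(R::unif_rand() * 3.0);
        int delta = (R::unif_rand() < 0.5) ? -step : step;
        m.Lat(r, t) = old + delta;
        m.set_next_state(t);
        double prop = m.proc_lp(t) + m.carc_lp(t) + m.downstream_lp(t);
        lat_try += 1.0;
        if (std::log(R::unif_rand()) < prop - cur) {
          lat_acc += 1.0;
          cur = prop;
        } else {
          m.Lat(r, t) = old;
          m.set_next_state(t);
        }
      }
    }

    // -- per-transition forward block resimulation -----------------------
    for (int t = 0; t < T1; ++t) {
      double cur = m.carc_lp(t) + m.downstream_lp(t);
      int saved[15];
      for (int r = 0; r < 15; ++r) saved[r] = m.Lat(r, t);
      Rates rt = m.rates(t);
      m.Lat(0, t) = (int)R::rbinom(m.N(4, t), rt.s1);
      m.Lat(1, t) = (int)R::rbinom(m.N(2, t), rt.s4);
      m.Lat(2, t) = (int)R::rbinom(m.N(3, t), rt.sp);
      m.Lat(3, t) = (int)R::rbinom(m.N(4, t), rt.sa);
      m.Lat(4, t) = (int)R::rbinom(m.N(5, t), rt.sa);
      m.Lat(5, t) = (int)R::rbinom(m.N(8, t), rt.s4);
      m.Lat(6, t) = (int)R::rbinom(m.N(9, t), rt.sa);
      m.Lat(7, t) = (int)R::rbinom(m.Lat(1, t), rt.g4);
      m.Lat(8, t) = (int)R::rbinom(m.Lat(2, t), rt.gp);
      m.Lat(9, t) = (int)R::rbinom(m.Lat(4, t), rt.gb);
      m.Lat(10, t) = (int)R::rbinom(m.Lat(0, t), 0.5);
      m.Lat(11, t) = (int)R::rbinom(m.N(0, t), rt.s2);
      m.Lat(12, t) = (int)R::rbinom(m.N(1, t), rt.s3);
      m.Lat(13, t) = (int)R::rbinom(m.N(6, t), rt.s2);
      m.Lat(14, t) = (int)R::rbinom(m.N(7, t), rt.s3);
      m.set_next_state(t);
      double prop = m.carc_lp(t) + m.downstream_lp(t);
      blk_try += 1.0;
      if (std::log(R::unif_rand()) < prop - cur) {
        blk_acc += 1.0;
      } else {
        for (int r = 0; r < 15; ++r) m.Lat(r, t) = saved[r];
        m.set_next_state(t);
      }
    }

    // -- survivor-chain shifts (trajectory-level mixing) -----------------
    // Shifting Sp, Sb, or Sma jointly from transition t0 to the end
    // slides an adult stage's abundance in all later years while
    // changing the death tally only in year t0.
    {
      static const int chain_rows[3] = {2, 4, 6};
      for (int rep = 0; rep < 12; ++rep) {
        int t0 = (int)(R::unif_rand() * T1);
        int r = chain_rows[(int)(R::unif_rand() * 3.0)];
        int step = 1 + (int)(R::unif_rand() * chain_k);
        int k = (R::unif_rand() < 0.5) ? -step : step;
        double cur = m.chain_local_lp(t0);
        for (int t = t0; t < T1; ++t) m.Lat(r, t) += k;
        for (int t = t0; t < T1; ++t) m.set_next_state(t);
        double prop = m.chain_local_lp(t0);
        chain_try += 1.0;
        blk_try += 1.0;
        if (std::log(R::unif_rand()) < prop - cur) {
          chain_acc += 1.0;
          blk_acc += 1.0;
        } else {
          for (int t = t0; t < T1; ++t) m.Lat(r, t) -= k;
          for (int t = t0; t < T1; ++t) m.set_next_state(t);
        }
      }
    }

    // -- birth-pulse moves (growth-level mixing) -------------------------
    for (int rep = 0; rep < 2; ++rep) {
      for (int t0 = 0; t0 < T1; ++t0) {
        int step = 1 + (int)(R::unif_rand() * birth_k);
        int k = (R::unif_rand() < 0.5) ? -step : step;
        double cur = m.cohort_local_lp(t0);
        m.shift_births(t0, k);
        double prop = m.cohort_local_lp(t0);
        birth_try += 1.0;
        blk_try += 1.0;
        if (std::log(R::unif_rand()) < prop - cur) {
          birth_acc += 1.0;
          blk_acc += 1.0;
        } else {
          m.shift_births(t0, -k);
        }
      }
    }

    // -- windowed survivor-chain shifts ----------------------------------
    // Moving a death from year t0 to year t1 while shifting the stage
    // level only in between lets the death series mix without moving
    // the whole-trajectory level.
    {
      static const int win_rows[3] = {2, 4, 6};
      for (int rep = 0; rep < T1; ++rep) {
        int t0 = (int)(R::unif_rand() * T1);
        int t1 = (int)(R::unif_rand() * T1);
        if (t0 == t1) continue;
        if (t0 > t1) { int tmp = t0; t0 = t1; t1 = tmp; }
        int r = win_rows[(int)(R::unif_rand() * 3.0)];
        int step = 1 + (int)(R::unif_rand() * 3.0);
        int k = (R::unif_rand() < 0.5) ? -step : step;
        auto win_lp = [&]() {
          double lp = 0.0;
          for (int t = t0; t <= t1 && t < T1; ++t)
            lp += m.proc_lp(t) + m.carc_lp(t);
          for (int y = t0 + 1; y <= t1; ++y) lp += m.year_data_lp(y);
          return lp;
        };
        double cur = win_lp();
        for (int t = t0; t < t1; ++t) m.Lat(r, t) += k;
        for (int t = t0; t < t1; ++t) m.set_next_state(t);
        double prop = win_lp();
        blk_try += 1.0;
        if (std::log(R::unif_rand()) < prop - cur) {
          blk_acc += 1.0;
        } else {
          for (int t = t0; t < t1; ++t) m.Lat(r, t) -= k;
          for (int t = t0; t < t1; ++t) m.set_next_state(t);
        }
      }
    }

    // -- ancestral refresh -----------------------------------------------
    // Propose the initial census (lN0, w) and the entire latent
    // trajectory from the prior process; prior and process cancel in
    // the Hastings ratio, leaving only the data terms. With no data
    // blocks this is exact ancestral sampling (always accepted), which
    // is what makes prior-only runs mix; with data it is an occasional
    // long-range jump.
    {
      auto data_lp = [&]() {
        double lp = 0.0;
        for (int t = 0; t < T1; ++t) lp += m.carc_lp(t);
        for (int y = 0; y < T; ++y) lp += m.year_data_lp(y);
        return lp;
      };
      double cur = data_lp();
      double old_lN0 = m.par[m.off_lN0];
      double old_w[10];
      for (int i = 0; i < 10; ++i) old_w[i] = m.par[m.off_w + i];
      std::vector<int> old_L(m.L);
      m.par[m.off_lN0] = m.init_mu + R::norm_rand() * m.init_sd;
      for (int i = 0; i < 10; ++i)
        m.par[m.off_w + i] = std::log(R::rgamma(m.dir_alpha[i], 1.0) + 1e-12);
      m.set_initial_state();
      for (int t = 0; t < T1; ++t) {
        Rates rt = m.rates(t);
        m.Lat(0, t) = (int)R::rbinom(m.N(4, t), rt.s1);
        m.Lat(1, t) = (int)R::rbinom(m.N(2, t), rt.s4);
        m.Lat(2, t) = (int)R::rbinom(m.N(3, t), rt.sp);
        m.Lat(3, t) = (int)R::rbinom(m.N(4, t), rt.sa);
        m.Lat(4, t) = (int)R::rbinom(m.N(5, t), rt.sa);
        m.Lat(5, t) = (int)R::rbinom(m.N(8, t), rt.s4);
        m.Lat(6, t) = (int)R::rbinom(m.N(9, t), rt.sa);
        m.Lat(7, t) = (int)R::rbinom(m.Lat(1, t), rt.g4);
        m.Lat(8, t) = (int)R::rbinom(m.Lat(2, t), rt.gp);
        m.Lat(9, t) = (int)R::rbinom(m.Lat(4, t), rt.gb);
        m.Lat(10, t) = (int)R::rbinom(m.Lat(0, t), 0.5);
        m.Lat(11, t) = (int)R::rbinom(m.N(0, t), rt.s2);
        m.Lat(12, t) = (int)R::rbinom(m.N(1, t), rt.s3);
        m.Lat(13, t) = (int)R::rbinom(m.N(6, t), rt.s2);
        m.Lat(14, t) = (int)R::rbinom(m.N(7, t), rt.s3);
        m.set_next_state(t);
      }
      double prop = data_lp();
      if (std::log(R::unif_rand()) < prop - cur) {
        // accepted
      } else {
        m.par[m.off_lN0] = old_lN0;
        for (int i = 0; i < 10; ++i) m.par[m.off_w + i] = old_w[i];
        m.L = old_L;
        m.rebuild_states();
      }
    }

    // -- joint level move ------------------------------------------------
    // Shift the initial abundance and slide the adult survivor chains
    // (Sp, Sb, Sma) by the resulting stage deltas across the whole
    // span: the population level moves while adult death tallies stay
    // fixed; only year-1 deaths of the uncompensated stages change.
    for (int rep = 0; rep < 4; ++rep) {
      auto level_lp = [&]() {
        double lp = R::dnorm(m.par[m.off_lN0], m.init_mu, m.init_sd, 1) +
                    m.carc_lp(0);
        for (int t = 0; t < T1; ++t) lp += m.proc_lp(t);
        for (int y = 0; y < T; ++y) lp += m.year_data_lp(y);
        return lp;
      };
      double cur = level_lp();
      double old_lN0 = m.par[m.off_lN0];
      int old_n1[10];
      for (int s = 0; s < 10; ++s) old_n1[s] = m.N(s, 0);
      double delta = R::norm_rand() * level_scale;
      m.par[m.off_lN0] = old_lN0 + delta;
      m.set_initial_state();
      int d_p = m.N(3, 0) - old_n1[3];
      int d_b = m.N(5, 0) - old_n1[5];
      int d_ma = m.N(9, 0) - old_n1[9];
      for (int t = 0; t < T1; ++t) {
        m.Lat(2, t) += d_p;
        m.Lat(4, t) += d_b;
        m.Lat(6, t) += d_ma;
      }
      for (int t = 0; t < T1; ++t) m.set_next_state(t);
      double prop = level_lp();
      level_try += 1.0;
      if (std::log(R::unif_rand()) < prop - cur) {
        level_acc += 1.0;
      } else {
        m.par[m.off_lN0] = old_lN0;
        m.set_initial_state();
        for (int t = 0; t < T1; ++t) {
          m.Lat(2, t) -= d_p;
          m.Lat(4, t) -= d_b;
          m.Lat(6, t) -= d_ma;
        }
        for (int t = 0; t < T1; ++t) m.set_next_state(t);
      }
    }

    // -- continuous parameters -------------------------------------------
    for (int t = 0; t < T1; ++t) {
      int j = m.off_lsa + t;
      mh_scalar(j, [&]() {
        return R::dnorm(m.par[j], m.sa_mu[t], m.sa_sd[t], 1) + m.proc_lp(t);
      }, noop);
      int jb = m.off_lgb + t;
      mh_scalar(jb, [&]() {
        return R::dnorm(m.par[jb], m.gb_mu[t], m.gb_sd[t], 1) + m.proc_lp(t);
      }, noop);
    }
    {
      int j = m.off_lg4;
      mh_scalar(j, [&]() {
        double lp = R::dnorm(m.par[j], m.g4_mu, m.g4_sd, 1);
        for (int t = 0; t < T1; ++t) lp += m.proc_lp(t);
        return lp;
      }, noop);
    }
    for (int k = 0; k < 4; ++k) {
      int j = m.off_lrho + k;
      mh_scalar(j, [&]() {
        double lp = R::dnorm(m.par[j], m.rho_mu[k], m.rho_sd[k], 1);
        for (int t = 0; t < T1; ++t) lp += m.proc_lp(t);
        return lp;
      }, noop);
    }
    if (est_r) {
      for (int s = 0; s < 3; ++s) {
        int j = m.off_a + s;
        mh_scalar(j, [&]() {
          double lp = R::dnorm(m.par[j], m.a_mu, m.a_sd, 1);
          for (int t = 0; t < T1; ++t) lp += m.carc_lp(t);
          return lp;
        }, noop);
      }
      for (int t = 0; t < T1; ++t) {
        int j = m.off_eps + t;
        mh_scalar(j, [&]() {
          double sigma = std::exp(m.par[m.off_lsig]);
          return R::dnorm(m.par[j], 0.0, sigma, 1) + m.carc_lp(t);
        }, noop);
      }
      {
        int j = m.off_lsig;
        mh_scalar(j, [&]() {
          double sigma = std::exp(m.par[j]);
          double lp = M_LN2 + R::dnorm(sigma, 0.0, m.sig_scale, 1) + m.par[j];
          for (int t = 0; t < T1; ++t)
            lp += R::dnorm(m.par[m.off_eps + t], 0.0, sigma, 1);
          return lp;
        }, noop);
      }
    }
    {
      int j = m.off_lN0;
      mh_scalar(j, [&]() {
        return R::dnorm(m.par[j], m.init_mu, m.init_sd, 1) + m.proc_lp(0) +
               m.carc_lp(0) + m.year_data_lp(0);
      }, refresh_init);
    }
    for (int i = 0; i < 10; ++i) {
      int j = m.off_w + i;
      mh_scalar(j, [&]() {
        double a = m.dir_alpha[i], w = m.par[j];
        return a * w - std::exp(w) - std::lgamma(a) + m.proc_lp(0) +
               m.carc_lp(0) + m.year_data_lp(0);
      }, refresh_init);
    }

    // -- proposal-scale adaptation during burn-in ------------------------
    if (iter <= n_burn && iter % 50 == 0) {
      double gain = std::min(0.3, 2.0 / std::sqrt((double)(iter / 50)));
      for (int j = 0; j < m.n_par; ++j) {
        if (trials[j] > 0.0) {
          double rate = acc[j] / trials[j];
          scale[j] *= std::exp(gain * (rate - 0.44));
          scale[j] = std::min(std::max(scale[j], 1e-4), 50.0);
          acc[j] = trials[j] = 0.0;
        }
      }
      if (level_try > 0.0) {
        double rate = level_acc / level_try;
        level_scale *= std::exp(gain * (rate - 0.25));
        level_scale = std::min(std::max(level_scale, 1e-4), 1.0);
        level_acc = level_try = 0.0;
      }
      if (birth_try > 0.0) {
        birth_k *= std::exp(gain * (birth_acc / birth_try - 0.3));
        birth_k = std::min(std::max(birth_k, 1.0), 10.0);
        birth_acc = birth_try = 0.0;
      }
      if (chain_try > 0.0) {
        chain_k *= std::exp(gain * (chain_acc / chain_try - 0.3));
        chain_k = std::min(std::max(chain_k, 1.0), 10.0);
        chain_acc = chain_try = 0.0;
      }
    }

    // -- record ----------------------------------------------------------
    if (iter > n_burn && (iter - n_burn) % thin == 0 && row < n_keep) {
      int c = 0;
      for (int t = 0; t < T1; ++t) out(row, c++) = plogis_(m.par[m.off_lsa + t]);
      for (int t = 0; t < T1; ++t) out(row, c++) = plogis_(m.par[m.off_lgb + t]);
      out(row, c++) = plogis_(m.par[m.off_lg4]);
      for (int k = 0; k < 4; ++k) out(row, c++) = std::exp(m.par[m.off_lrho + k]);
      for (int s = 0; s < 3; ++s) out(row, c++) = m.par[m.off_a + s];
      out(row, c++) = std::exp(m.par[m.off_lsig]);
      for (int s = 0; s < 3; ++s)
        for (int t = 0; t < T1; ++t) out(row, c++) = m.recov(s, t);
      for (int y = 0; y < T; ++y) out(row, c++) = m.Ntot(y);
      double M[3];
      for (int s = 0; s < 3; ++s)
        for (int t = 0; t < T1; ++t) { m.deaths(t, M); out(row, c++) = M[s]; }
      for (int s = 0; s < 10; ++s)
        for (int y = 0; y < T; ++y) out(row, c++) = m.N(s, y);
      out(row, c++) = m.total_lp();
      ++row;
    }
  }

  NumericVector final_par(m.par.begin(), m.par.end());
  IntegerMatrix final_lat(15, T1);
  for (int t = 0; t < T1; ++t)
    for (int r = 0; r < 15; ++r) final_lat(r, t) = m.Lat(r, t);
  return List::create(
    _["samples"] = out,
    _["accept_latent"] = lat_try > 0 ? lat_acc / lat_try : NA_REAL,
    _["accept_block"] = blk_try > 0 ? blk_acc / blk_try : NA_REAL,
    _["accept_level"] = level_try > 0 ? level_acc / level_try : NA_REAL,
    _["level_scale"] = level_scale,
    _["final_par"] = final_par,
    _["final_lat"] = final_lat,
    _["logpost"] = m.total_lp());
}
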
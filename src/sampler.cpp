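// Metropolis-within-Gibbs sampler core.
//
// One exported function runs one chain. Continuous parameters use Gaussian
// random walks on transformed (log / logit) scales with Robbins-Monro
// step-size adaptation frozen at the end of burn-in; latent integers
// (initial abundance, yearly deaths and recruits) use symmetric integer
// random walks; the inclusion parameter of the initial-abundance binomial
// is updated by its conjugate beta Gibbs draw. The capture-history
// likelihood is the exact marginal over latent alive states and the yearly
// three-state availability draw, computed by a forward recursion with
// per-year emission lookup tables. The R-level joint_logposterior() is the
// reference implementation; the test suite asserts this core reproduces it
// on every saved draw.

#include <Rcpp.h>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct ModelCfg {
  int model;          // 0 = 1a, 1 = 1b, 2, 3, 4
  bool change;
  int T_BP;
  int N_max;
  double phi_lo, phi_hi, rho_lo, rho_hi, chi_lo;
  double ups_lo, ups_hi, b_sd, s_lo, s_hi;
  bool exponential() const { return model <= 1; }
  bool habitat() const { return model >= 1; }
  bool has_calf() const { return model >= 2; }
  bool has_capture() const { return model >= 3; }
  bool has_sb() const { return model == 4; }
};

struct Data {
  int T, K, n_sy;
  double Sx2, x_max, l, A, g0;
  int J;
  IntegerVector sy;          // survey years (1-based), length n_sy
  NumericVector S_t;         // total count per survey year
  IntegerVector n_counts;    // per surveyed cell-year
  IntegerVector count_cell;  // 1-based cell index
  IntegerVector count_sy;    // 0-based index into sy
  double lgamma_const;       // sum lgamma(n + 1)
  LogicalVector region;      // K
  IntegerMatrix target;      // K x T 0/1
  NumericMatrix H;           // K x T
  NumericVector p_id_t;      // T
  IntegerVector calf_year;
  IntegerVector calf_nc;
  IntegerVector calf_N;
  int n_ind, M;
  IntegerVector first;       // 1-based first capture year
  IntegerMatrix Ys;          // n_ind x T (0/1 survey captures)
  IntegerMatrix Sbc;         // n_ind x T (small-boat capture counts)
  int n_region;
  double count_HW;           // sum over count data of n * H[cell, year]
  std::vector<double> lgam;  // lgamma(0..N_max+1) table
  double lchoose_t(int n, int k) const {
    return lgam[n + 1] - lgam[k + 1] - lgam[n - k + 1];
  }
};

// b-dependent quantities, kept outside State so proposals that do not touch
// b never copy the K x T distribution surface
struct Cache {
  std::vector<double> P_t;   // region share of distribution per survey year
  std::vector<double> pa1, pa2, pa3; // per year
  double Q;                  // sum n log pk over count data
};

struct State {
  double s, b, zeta, phi1, phi2, rho, chi, p_r_sb, N1c, ups1, ups2;
  std::vector<int> N;        // length T (binomial models)
  std::vector<int> D, R;     // length T - 1
  std::vector<double> N_exp; // exponential-model trajectory
  double esw, p_d;
  double ll_dist, ll_counts, ll_calf, ll_cap, lp_proc, lp_prior;
  double logpost() const {
    return ll_dist + ll_counts + ll_calf + ll_cap + lp_proc + lp_prior;
  }
  double deviance() const {
    return -2.0 * (ll_dist + ll_counts + ll_calf + ll_cap);
  }
};

static double esw_halfnormal_c(double s, double x_max) {
  return s * std::sqrt(2.0 * M_PI) *
    (R::pnorm(x_max / s, 0.0, 1.0, 1, 0) - 0.5);
}

static void update_detection(State &st, const Data &d) {
  st.esw = esw_halfnormal_c(st.s, d.x_max);
  st.p_d = 2.0 * d.l * st.esw * d.g0 / d.A;
  if (st.p_d > 1.0) st.p_d = 1.0; // geometry validated on the R side
  st.ll_dist = (d.J > 0)
    ? -d.Sx2 / (2.0 * st.s * st.s) - d.J * std::log(st.esw)
    : 0.0;
}

static void update_pk(Cache &ca, double b, const ModelCfg &m, const Data &d) {
  ca.P_t.assign(d.n_sy, 0.0);
  ca.pa1.assign(d.T, 0.0);
  ca.pa2.assign(d.T, 0.0);
  ca.pa3.assign(d.T, 0.0);
  if (!m.habitat()) {
    for (int j = 0; j < d.n_sy; ++j) ca.P_t[j] = 1.0;
    ca.Q = 0.0;
    for (int i = 0; i < d.n_counts.size(); ++i)
      ca.Q += d.n_counts[i] * std::log(1.0 / d.n_region);
    return;
  }
  // softmax sums per year; individual pk values are never needed, only
  // stratum sums and (for the counts) sum_data n log pk, which reduces to
  // b * sum(n H) - sum_t S_t (max_t + log tot_t)
  std::vector<double> log_norm(d.T, 0.0); // max_t + log(tot_t)
  bool need_all_years = m.has_capture();
  for (int t = 0; t < d.T; ++t) {
    bool needed = need_all_years;
    int j_sy = -1;
    for (int j = 0; j < d.n_sy; ++j) if (d.sy[j] - 1 == t) j_sy = j;
    if (j_sy >= 0) needed = true;
    if (!needed) continue;
    const double *Hcol = &d.H(0, t);
    double mx = NEG_INF;
    for (int k = 0; k < d.K; ++k) {
      double eta = b * Hcol[k];
      if (eta > mx) mx = eta;
    }
    double tot = 0.0, a1 = 0.0, areg = 0.0;
    for (int k = 0; k < d.K; ++k) {
      double e = std::exp(b * Hcol[k] - mx);
      tot += e;
      if (d.region[k]) areg += e;
      if (d.target(k, t)) a1 += e;
    }
    ca.pa1[t] = a1 / tot;
    ca.pa2[t] = (areg - a1) / tot;
    ca.pa3[t] = 1.0 - areg / tot;
    if (ca.pa3[t] < 0) ca.pa3[t] = 0;
    log_norm[t] = mx + std::log(tot);
    if (j_sy >= 0) ca.P_t[j_sy] = areg / tot;
  }
  ca.Q = b * d.count_HW;
  for (int j = 0; j < d.n_sy; ++j)
    ca.Q -= d.S_t[j] * log_norm[d.sy[j] - 1];
}

static double N_at(const State &st, const ModelCfg &m, int t) {
  return m.exponential() ? st.N_exp[t] : (double)st.N[t];
}

static void update_trajectory(State &st, const ModelCfg &m, const Data &d) {
  if (!m.exponential()) return;
  st.N_exp.assign(d.T, 0.0);
  st.N_exp[0] = st.N1c;
  for (int tau = 1; tau < d.T; ++tau) {
    double r = (m.change && tau >= m.T_BP) ? st.ups2 : st.ups1;
    st.N_exp[tau] = st.N_exp[tau - 1] * std::exp(r);
  }
}

static void update_counts(State &st, const Cache &ca, const ModelCfg &m,
                          const Data &d) {
  double ll = ca.Q - d.lgamma_const;
  double logpd = std::log(st.p_d);
  for (int j = 0; j < d.n_sy; ++j) {
    int t = d.sy[j] - 1;
    double N = N_at(st, m, t);
    if (d.S_t[j] > 0) {
      if (N <= 0 || ca.P_t[j] <= 0) { st.ll_counts = NEG_INF; return; }
      ll += d.S_t[j] * (std::log(N) + logpd);
    }
    ll += -st.p_d * N * ca.P_t[j];
  }
  st.ll_counts = ll;
}

static void update_calf(State &st, const ModelCfg &m, const Data &d) {
  if (!m.has_calf()) { st.ll_calf = 0.0; return; }
  double ll = 0.0;
  for (int i = 0; i < d.calf_year.size(); ++i) {
    double phi = (m.change && d.calf_year[i] > m.T_BP) ? st.phi2 : st.phi1;
    double p = st.rho / (st.rho * st.chi + phi);
    ll += R::dbinom(d.calf_nc[i], d.calf_N[i], p, 1);
  }
  st.ll_calf = ll;
}

static void update_capture(State &st, const Cache &ca, const ModelCfg &m,
                           const Data &d) {
  if (!m.has_capture()) { st.ll_cap = 0.0; return; }
  const int T = d.T, M = d.M;
  const bool sb = m.has_sb();
  // emission tables per year: e_alive[y][c], c in 0..M (c = 0 only if !sb)
  std::vector<double> tab((size_t)T * 2 * (M + 1), 0.0);
  for (int t = 1; t < T; ++t) {
    double pr = st.p_d * d.p_id_t[t]; // zero outside survey years
    double pa1 = ca.pa1[t], pa2 = ca.pa2[t], pa3 = ca.pa3[t];
    for (int y = 0; y <= 1; ++y) {
      double by12 = y ? pr : 1.0 - pr;
      double by3 = y ? 0.0 : 1.0;
      for (int c = 0; c <= (sb ? M : 0); ++c) {
        double bsb1 = 1.0, bsb23 = 1.0;
        if (sb) {
          bsb1 = std::pow(st.p_r_sb, c) * std::pow(1.0 - st.p_r_sb, M - c);
          bsb23 = (c == 0) ? 1.0 : 0.0;
        }
        tab[((size_t)t * 2 + y) * (M + 1) + c] =
          pa1 * by12 * bsb1 + pa2 * by12 * bsb23 + pa3 * by3 * bsb23;
      }
    }
  }
  double ll = 0.0;
  for (int i = 0; i < d.n_ind; ++i) {
    int t0 = d.first[i]; // 1-based; forward starts at year t0 + 1
    if (t0 >= T) continue;
    double wa = 1.0, wd = 0.0;
    for (int t = t0; t < T; ++t) { // 0-based year index
      double phi = (m.change && (t + 1) > m.T_BP) ? st.phi2 : st.phi1;
      wd += wa * (1.0 - phi);
      wa *= phi;
      int y = d.Ys(i, t);
      int c = sb ? d.Sbc(i, t) : 0;
      wa *= tab[((size_t)t * 2 + y) * (M + 1) + c];
      if (y != 0 || c != 0) wd = 0.0;
    }
    double tot = wa + wd;
    if (tot <= 0) { st.ll_cap = NEG_INF; return; }
    ll += std::log(tot);
  }
  st.ll_cap = ll;
}

static void update_process(State &st, const ModelCfg &m, const Data &d) {
  if (m.exponential()) { st.lp_proc = 0.0; return; }
  double lp = R::dbinom(st.N[0], m.N_max, st.zeta, 1);
  double l1mphi1 = std::log(1.0 - st.phi1), lphi1 = std::log(st.phi1);
  double l1mphi2 = m.change ? std::log(1.0 - st.phi2) : l1mphi1;
  double lphi2 = m.change ? std::log(st.phi2) : lphi1;
  double rc = st.rho * st.chi;
  double lrc = std::log(rc), l1mrc = std::log1p(-rc);
  for (int tau = 0; tau < d.T - 1; ++tau) {
    bool late = m.change && tau + 1 >= m.T_BP;
    int Np = st.N[tau];
    int D = st.D[tau], R = st.R[tau];
    if (D < 0 || D > Np || R < 0 || R > Np) {
      st.lp_proc = NEG_INF; return;
    }
    lp += d.lchoose_t(Np, D) + D * (late ? l1mphi2 : l1mphi1) +
      (Np - D) * (late ? lphi2 : lphi1);
    lp += d.lchoose_t(Np, R) + R * lrc + (Np - R) * l1mrc;
    int Nn = Np - D + R;
    if (Nn < 0 || Nn > m.N_max) { st.lp_proc = NEG_INF; return; }
    st.N[tau + 1] = Nn;
  }
  st.lp_proc = lp;
}

static void update_prior(State &st, const ModelCfg &m) {
  double lp = -std::log(m.s_hi - m.s_lo);
  if (m.habitat()) lp += R::dnorm(st.b, 0.0, m.b_sd, 1);
  if (m.exponential()) {
    lp += -std::log((double)m.N_max);
    lp += -std::log(m.ups_hi - m.ups_lo) * (m.change ? 2.0 : 1.0);
  } else {
    lp += -std::log(m.phi_hi - m.phi_lo) * (m.change ? 2.0 : 1.0);
    lp += -std::log(m.rho_hi - m.rho_lo);
    double phimin = m.change ? std::min(st.phi1, st.phi2) : st.phi1;
    lp += -std::log(phimin - m.chi_lo);
  }
  st.lp_prior = lp;
}

static bool in_support(const State &st, const ModelCfg &m) {
  if (st.s <= m.s_lo || st.s >= m.s_hi) return false;
  if (m.exponential()) {
    if (st.N1c <= 0 || st.N1c > m.N_max) return false;
    if (st.ups1 <= m.ups_lo || st.ups1 >= m.ups_hi) return false;
    if (m.change && (st.ups2 <= m.ups_lo || st.ups2 >= m.ups_hi)) return false;
  } else {
    if (st.phi1 <= m.phi_lo || st.phi1 >= m.phi_hi) return false;
    if (m.change && (st.phi2 <= m.phi_lo || st.phi2 >= m.phi_hi)) return false;
    if (st.rho <= m.rho_lo || st.rho >= m.rho_hi) return false;
    double phimin = m.change ? std::min(st.phi1, st.phi2) : st.phi1;
    if (st.chi <= m.chi_lo || st.chi >= phimin) return false;
    if (st.zeta <= 0 || st.zeta >= 1) return false;
    if (st.N[0] < 0 || st.N[0] > m.N_max) return false;
    if (m.has_sb() && (st.p_r_sb <= 0 || st.p_r_sb >= 1)) return false;
  }
  return true;
}

static double to_z(double theta, double lo, double hi) {
  double u = (theta - lo) / (hi - lo);
  return std::log(u / (1.0 - u));
}
static double from_z(double z, double lo, double hi) {
  double u = 1.0 / (1.0 + std::exp(-z));
  return lo + (hi - lo) * u;
}
static double logjac_z(double z, double lo, double hi) {
  double u = 1.0 / (1.0 + std::exp(-z));
  return std::log(hi - lo) + std::log(u) + std::log(1.0 - u);
}

enum Block {
  B_S, B_B, B_PHI1, B_PHI2, B_RHO, B_CHI, B_PRSB,
  B_N1C, B_UPS1, B_UPS2, B_N1, B_NBLOCK
};

// [[Rcpp::export]]
List cpp_run_chain(List model, List data, List mcmc, List init,
                   NumericVector step_init) {
  ModelCfg m;
  m.model = as<int>(model["model"]);
  m.change = as<bool>(model["change"]);
  m.T_BP = as<int>(model["T_BP"]);
  m.N_max = as<int>(model["N_max"]);
  NumericVector pb = model["phi_bounds"], rb = model["rho_bounds"],
    ub = model["upsilon_bounds"], sbnd = model["s_bounds"];
  m.phi_lo = pb[0]; m.phi_hi = pb[1];
  m.rho_lo = rb[0]; m.rho_hi = rb[1];
  m.chi_lo = as<double>(model["chi_lower"]);
  m.ups_lo = ub[0]; m.ups_hi = ub[1];
  m.b_sd = as<double>(model["b_sd"]);
  m.s_lo = sbnd[0]; m.s_hi = sbnd[1];

  Data d;
  d.T = as<int>(data["T"]);
  d.K = as<int>(data["K"]);
  d.Sx2 = as<double>(data["Sx2"]);
  d.J = as<int>(data["J"]);
  d.x_max = as<double>(data["x_max"]);
  d.l = as<double>(data["l"]);
  d.A = as<double>(data["A"]);
  d.g0 = as<double>(data["g0"]);
  d.sy = data["sy"];
  d.n_sy = d.sy.size();
  d.S_t = data["S_t"];
  d.n_counts = data["n_counts"];
  d.count_cell = data["count_cell"];
  d.count_sy = data["count_sy"];
  d.lgamma_const = as<double>(data["lgamma_const"]);
  d.region = data["region"];
  d.target = as<IntegerMatrix>(data["target"]);
  d.H = as<NumericMatrix>(data["H"]);
  d.p_id_t = data["p_id_t"];
  d.calf_year = data["calf_year"];
  d.calf_nc = data["calf_nc"];
  d.calf_N = data["calf_N"];
  d.n_ind = as<int>(data["n_ind"]);
  d.M = as<int>(data["M"]);
  d.first = data["first"];
  d.Ys = as<IntegerMatrix>(data["Ys"]);
  d.Sbc = as<IntegerMatrix>(data["Sbc"]);
  d.n_region = 0;
  for (int k = 0; k < d.K; ++k) if (d.region[k]) ++d.n_region;
  d.count_HW = 0.0;
  for (int i = 0; i < d.n_counts.size(); ++i) {
    int t = d.sy[d.count_sy[i]] - 1;
    d.count_HW += d.n_counts[i] * d.H(d.count_cell[i] - 1, t);
  }
  d.lgam.resize(m.N_max + 3);
  for (int i = 0; i < (int)d.lgam.size(); ++i)
    d.lgam[i] = std::lgamma((double)i);

  int n_iter = as<int>(mcmc["n_iter"]);
  int burn_in = as<int>(mcmc["burn_in"]);
  int thin = as<int>(mcmc["thin"]);

  State st;
  st.s = as<double>(init["s"]);
  st.b = as<double>(init["b"]);
  st.zeta = as<double>(init["zeta"]);
  st.phi1 = as<double>(init["phi1"]);
  st.phi2 = as<double>(init["phi2"]);
  st.rho = as<double>(init["rho"]);
  st.chi = as<double>(init["chi"]);
  st.p_r_sb = as<double>(init["p_r_sb"]);
  st.N1c = as<double>(init["N1c"]);
  st.ups1 = as<double>(init["ups1"]);
  st.ups2 = as<double>(init["ups2"]);
  st.N.assign(d.T, 0);
  st.D.assign(d.T - 1, 0);
  st.R.assign(d.T - 1, 0);
  if (!m.exponential()) {
    st.N[0] = as<int>(init["N1"]);
    IntegerVector D0 = init["D"], R0 = init["R"];
    for (int i = 0; i < d.T - 1; ++i) { st.D[i] = D0[i]; st.R[i] = R0[i]; }
  }
  Cache ca, ca_prop;
  update_detection(st, d);
  update_pk(ca, st.b, m, d);
  update_trajectory(st, m, d);
  update_process(st, m, d);
  update_counts(st, ca, m, d);
  update_calf(st, m, d);
  update_capture(st, ca, m, d);
  update_prior(st, m);
  if (!std::isfinite(st.logpost()))
    stop("non-finite log-posterior at initialization");

  std::vector<double> lstep(B_NBLOCK, 0.0);
  for (int b = 0; b < B_NBLOCK; ++b) lstep[b] = std::log(step_init[b]);
  double lstep_lat = std::log(step_init[B_NBLOCK]);
  std::vector<int> acc(B_NBLOCK + 1, 0), tries(B_NBLOCK + 1, 0);

  int n_save = (n_iter - burn_in) / thin;
  int n_par = 11;
  int ncol = n_par + d.T + 2 * (d.T - 1) + 4;
  NumericMatrix draws(n_save, ncol);
  int row = 0;

  State prop_st;
  for (int iter = 1; iter <= n_iter; ++iter) {
    bool adapting = iter <= burn_in;
    double adapt_rate = 1.0 / std::sqrt((double)(iter / 50 + 1));

    for (int b = 0; b < B_NBLOCK; ++b) {
      bool active;
      switch (b) {
        case B_S: active = true; break;
        case B_B: active = m.habitat(); break;
        case B_PHI1: active = !m.exponential(); break;
        case B_PHI2: active = !m.exponential() && m.change; break;
        case B_RHO: case B_CHI: active = !m.exponential(); break;
        case B_PRSB: active = m.has_sb(); break;
        case B_N1C: case B_UPS1: active = m.exponential(); break;
        case B_UPS2: active = m.exponential() && m.change; break;
        case B_N1: active = !m.exponential(); break;
        default: active = false;
      }
      if (!active) continue;
      ++tries[b];
      prop_st = st;
      double step = std::exp(lstep[b]);
      double lj_old = 0.0, lj_new = 0.0;
      bool ok = true;
      if (b == B_N1) {
        int w = std::max(1, (int)std::lround(step));
        int delta = (int)std::floor(unif_rand() * (2 * w + 1)) - w;
        prop_st.N[0] = st.N[0] + delta;
        if (prop_st.N[0] < 0 || prop_st.N[0] > m.N_max) ok = false;
      } else {
        double z, znew, lo = 0, hi = 1;
        bool bounded = true;
        double *tgt = nullptr;
        switch (b) {
          case B_S: lo = m.s_lo; hi = m.s_hi; tgt = &prop_st.s; break;
          case B_B: bounded = false; tgt = &prop_st.b; break;
          case B_PHI1: lo = m.phi_lo; hi = m.phi_hi; tgt = &prop_st.phi1; break;
          case B_PHI2: lo = m.phi_lo; hi = m.phi_hi; tgt = &prop_st.phi2; break;
          case B_RHO: lo = m.rho_lo; hi = m.rho_hi; tgt = &prop_st.rho; break;
          case B_CHI: lo = m.chi_lo; hi = 1.0; tgt = &prop_st.chi; break;
          case B_PRSB: lo = 0.0; hi = 1.0; tgt = &prop_st.p_r_sb; break;
          case B_N1C: lo = 0.0; hi = (double)m.N_max; tgt = &prop_st.N1c; break;
          case B_UPS1: lo = m.ups_lo; hi = m.ups_hi; tgt = &prop_st.ups1; break;
          case B_UPS2: lo = m.ups_lo; hi = m.ups_hi; tgt = &prop_st.ups2; break;
          default: ok = false;
        }
        if (ok) {
          if (bounded) {
            z = to_z(*tgt, lo, hi);
            znew = z + step * norm_rand();
            *tgt = from_z(znew, lo, hi);
            lj_old = logjac_z(z, lo, hi);
            lj_new = logjac_z(znew, lo, hi);
          } else {
            *tgt = *tgt + step * norm_rand();
          }
        }
      }
      bool accepted = false;
      if (ok && in_support(prop_st, m)) {
        bool use_prop_cache = (b == B_B);
        const Cache &cc = use_prop_cache ? ca_prop : ca;
        if (use_prop_cache) update_pk(ca_prop, prop_st.b, m, d);
        switch (b) {
          case B_S:
            update_detection(prop_st, d);
            update_counts(prop_st, cc, m, d);
            update_capture(prop_st, cc, m, d);
            update_prior(prop_st, m);
            break;
          case B_B:
            update_counts(prop_st, cc, m, d);
            update_capture(prop_st, cc, m, d);
            update_prior(prop_st, m);
            break;
          case B_PHI1: case B_PHI2:
            update_process(prop_st, m, d);
            update_counts(prop_st, cc, m, d);
            update_calf(prop_st, m, d);
            update_capture(prop_st, cc, m, d);
            update_prior(prop_st, m);
            break;
          case B_RHO: case B_CHI:
            update_process(prop_st, m, d);
            update_counts(prop_st, cc, m, d);
            update_calf(prop_st, m, d);
            break;
          case B_PRSB:
            update_capture(prop_st, cc, m, d);
            break;
          case B_N1C: case B_UPS1: case B_UPS2:
            update_trajectory(prop_st, m, d);
            update_counts(prop_st, cc, m, d);
            break;
          case B_N1:
            update_process(prop_st, m, d);
            update_counts(prop_st, cc, m, d);
            break;
        }
        double la = prop_st.logpost() - st.logpost() + lj_new - lj_old;
        if (std::isfinite(prop_st.logpost()) &&
            std::log(unif_rand()) < la) {
          st = prop_st;
          if (use_prop_cache) std::swap(ca, ca_prop);
          accepted = true;
        }
      }
      if (accepted) ++acc[b];
      if (adapting) {
        lstep[b] += adapt_rate * ((accepted ? 1.0 : 0.0) - 0.44);
        if (b == B_N1 && lstep[b] < 0.0) lstep[b] = 0.0; // window >= 1
      }
    }

    // zeta: conjugate Gibbs draw (uniform prior, binomial N1)
    if (!m.exponential()) {
      st.zeta = R::rbeta(st.N[0] + 1.0, m.N_max - st.N[0] + 1.0);
      if (st.zeta <= 0) st.zeta = 1e-12;
      if (st.zeta >= 1) st.zeta = 1.0 - 1e-12;
      update_process(st, m, d);
    }

    // latent deaths/recruits sweep
    if (!m.exponential()) {
      int w = std::max(1, (int)std::lround(std::exp(lstep_lat)));
      int n_acc = 0, n_try = 0;
      for (int tau = 0; tau < d.T - 1; ++tau) {
        for (int which = 0; which < 2; ++which) {
          ++n_try;
          prop_st = st;
          int delta = (int)std::floor(unif_rand() * (2 * w + 1)) - w;
          if (which == 0) prop_st.D[tau] += delta;
          else prop_st.R[tau] += delta;
          update_process(prop_st, m, d);
          update_counts(prop_st, ca, m, d);
          double la = prop_st.logpost() - st.logpost();
          if (std::isfinite(prop_st.logpost()) &&
              std::log(unif_rand()) < la) {
            st = prop_st;
            ++n_acc;
          }
        }
      }
      tries[B_NBLOCK] += n_try;
      acc[B_NBLOCK] += n_acc;
      if (adapting) {
        lstep_lat += adapt_rate * ((double)n_acc / n_try - 0.44);
        if (lstep_lat < 0.0) lstep_lat = 0.0;
      }
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      int c = 0;
      draws(row, c++) = st.s;
      draws(row, c++) = st.b;
      draws(row, c++) = st.zeta;
      draws(row, c++) = st.phi1;
      draws(row, c++) = m.change ? st.phi2 : st.phi1;
      draws(row, c++) = st.rho;
      draws(row, c++) = st.chi;
      draws(row, c++) = st.p_r_sb;
      draws(row, c++) = st.N1c;
      double u1, u2;
      if (m.exponential()) {
        u1 = st.ups1;
        u2 = m.change ? st.ups2 : st.ups1;
      } else {
        u1 = std::log(st.rho * st.chi + st.phi1);
        u2 = std::log(st.rho * st.chi + (m.change ? st.phi2 : st.phi1));
      }
      draws(row, c++) = u1;
      draws(row, c++) = u2;
      for (int t = 0; t < d.T; ++t) draws(row, c++) = N_at(st, m, t);
      for (int t = 0; t < d.T - 1; ++t)
        draws(row, c++) = m.exponential() ? NA_REAL : st.D[t];
      for (int t = 0; t < d.T - 1; ++t)
        draws(row, c++) = m.exponential() ? NA_REAL : st.R[t];
      draws(row, c++) = m.change ? (u2 - u1) : NA_REAL;
      draws(row, c++) = st.deviance();
      draws(row, c++) = st.logpost();
      draws(row, c++) = st.lp_prior + st.lp_proc;
      ++row;
    }
  }

  NumericVector acc_rate(B_NBLOCK + 1);
  for (int b = 0; b <= B_NBLOCK; ++b)
    acc_rate[b] = tries[b] ? (double)acc[b] / tries[b] : NA_REAL;
  return List::create(
    _["draws"] = draws,
    _["acc"] = acc_rate,
    _["steps"] = NumericVector(lstep.begin(), lstep.end())
  );
}
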
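// Compiled core: channel propensities, deterministic right-hand side, and
// the per-vesicle SSA loop (Gillespie direct method, plus a hybrid mode that
// Poisson-leaps fast membrane/transport channels while keeping RNA chemistry
// exact through hazard accumulation).
//
// All quantities are in SI-with-litres units: lengths dm, surfaces dm^2,
// volumes dm^3 = L, concentrations mol/L, time s. Counts are molecule
// numbers (double-valued; integer-valued in stochastic mode).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// channel kinds
enum { K_REACT = 0, K_INFLUX = 1, K_EFFLUX = 2,
       K_UP_INT = 3, K_UP_EXT = 4, K_REL_INT = 5, K_REL_EXT = 6 };

struct Net {
  int nsp = 0, nch = 0;
  std::vector<int> kind, M, r1, r2, homo, sp, leap;
  std::vector<double> k;
  // stoichiometry, CSR by channel
  std::vector<int> sptr, sidx;
  std::vector<double> sdel;
  std::vector<int> osm;                       // per-species osmotic flag
  int iLaq = -1, iLmem = -1;                  // key species (0-based)
  int iUpInt = -1, iRelInt = -1, iSynth = -1; // key channels (0-based)
  std::vector<double> conc_ex;                // external conc per species (M)
  double C_L_ex = 0, C_T_E = 0;
  double NAv = 0, alpha_half = 0, v_aq = 0, P_aq = 0, k_in = 0, k_out = 0;
  double phi_div = 0, phi_burst = 0;
};

static inline double osm_sum(const Net& net, const std::vector<double>& n) {
  double s = 0;
  for (int i = 0; i < net.nsp; ++i) if (net.osm[i]) s += n[i];
  return s;
}

static inline double surface_of(const Net& net, const std::vector<double>& n) {
  return net.alpha_half * std::max(n[net.iLmem], 0.0);
}

static inline double phi_of(double S, double V) {
  return S / std::cbrt(36.0 * M_PI * V * V);
}

// Negative counts (transient solver states) contribute no flux. Species in
// an invariant zero subspace (e.g. a gene sector the vesicle never had) are
// protected against solver-noise seeding by the reachability mask in
// rc_det_rhs, not here: a hard sub-molecule cutoff in the rate laws would
// put step discontinuities inside the thinly-populated elongation ladder.
static inline double cnt(double x) { return (x > 0.0) ? x : 0.0; }

// propensities (stoch = true: integer counting with n(n-1) for the
// homo-bimolecular self-template channel; false: mass-action n^2)
static void calc_prop(const Net& net, const std::vector<double>& n, double V,
                      double S, bool stoch, std::vector<double>& a) {
  const double VN = V * net.NAv;
  for (int j = 0; j < net.nch; ++j) {
    double aj = 0;
    switch (net.kind[j]) {
    case K_REACT:
      if (net.M[j] == 1) {
        aj = net.k[j] * cnt(n[net.r1[j]]);
      } else {
        double x1 = cnt(n[net.r1[j]]), x2;
        if (net.homo[j]) x2 = stoch ? std::max(x1 - 1.0, 0.0) : x1;
        else x2 = cnt(n[net.r2[j]]);
        aj = net.k[j] / VN * x1 * x2;
      }
      break;
    case K_INFLUX:
      aj = net.k[j] * S * net.NAv * net.conc_ex[net.sp[j]];
      break;
    case K_EFFLUX:
      aj = net.k[j] * S * cnt(n[net.sp[j]]) / V;
      break;
    case K_UP_INT:
      aj = net.k[j] * S * cnt(n[net.iLaq]) / VN;
      break;
    case K_UP_EXT:
      aj = net.k[j] * S * net.C_L_ex;
      break;
    case K_REL_INT:
    case K_REL_EXT:
      aj = net.k[j] * std::max(n[net.iLmem], 0.0);
      break;
    }
    a[j] = aj;
  }
}

static inline void apply_channel(const Net& net, int j, double mult,
                                 std::vector<double>& n, bool skip_laq) {
  for (int p = net.sptr[j]; p < net.sptr[j + 1]; ++p) {
    int i = net.sidx[p];
    if (skip_laq && i == net.iLaq) continue;
    n[i] += mult * net.sdel[p];
  }
}

// [[Rcpp::export]]
SEXP rc_compile(List L) {
  Net* net = new Net();
  net->nsp = as<int>(L["nsp"]);
  net->nch = as<int>(L["nch"]);
  IntegerVector kind = L["kind"], M = L["M"], r1 = L["r1"], r2 = L["r2"],
    homo = L["homo"], sp = L["sp"], leap = L["leap"], sptr = L["sptr"],
    sidx = L["sidx"], osm = L["osm"];
  NumericVector k = L["k"], sdel = L["sdel"], conc_ex = L["conc_ex"];
  net->kind.assign(kind.begin(), kind.end());
  net->M.assign(M.begin(), M.end());
  net->homo.assign(homo.begin(), homo.end());
  net->leap.assign(leap.begin(), leap.end());
  net->k.assign(k.begin(), k.end());
  net->sdel.assign(sdel.begin(), sdel.end());
  net->conc_ex.assign(conc_ex.begin(), conc_ex.end());
  net->osm.assign(osm.begin(), osm.end());
  net->r1.resize(net->nch); net->r2.resize(net->nch); net->sp.resize(net->nch);
  for (int j = 0; j < net->nch; ++j) {  // 1-based -> 0-based, NA -> -1
    net->r1[j] = (r1[j] == NA_INTEGER) ? -1 : r1[j] - 1;
    net->r2[j] = (r2[j] == NA_INTEGER) ? -1 : r2[j] - 1;
    net->sp[j] = (sp[j] == NA_INTEGER) ? -1 : sp[j] - 1;
  }
  net->sptr.assign(sptr.begin(), sptr.end());
  net->sidx.resize(sidx.size());
  for (int p = 0; p < (int)sidx.size(); ++p) net->sidx[p] = sidx[p] - 1;
  for (int p = 0; p < (int)net->sptr.size(); ++p) net->sptr[p] -= 1;
  net->iLaq = as<int>(L["iLaq"]) - 1;
  net->iLmem = as<int>(L["iLmem"]) - 1;
  net->iUpInt = as<int>(L["iUpInt"]) - 1;
  net->iRelInt = as<int>(L["iRelInt"]) - 1;
  net->iSynth = as<int>(L["iSynth"]) - 1;
  net->C_L_ex = as<double>(L["C_L_ex"]);
  net->C_T_E = as<double>(L["C_T_E"]);
  net->NAv = as<double>(L["NAv"]);
  net->alpha_half = as<double>(L["alpha_half"]);
  net->v_aq = as<double>(L["v_aq"]);
  net->P_aq = as<double>(L["P_aq"]);
  net->k_in = as<double>(L["k_in"]);
  net->k_out = as<double>(L["k_out"]);
  net->phi_div = as<double>(L["phi_div"]);
  net->phi_burst = as<double>(L["phi_burst"]);
  return XPtr<Net>(net, true);
}

// [[Rcpp::export]]
NumericVector rc_propensities(SEXP xp, NumericVector counts, double V,
                              bool stoch) {
  XPtr<Net> net(xp);
  std::vector<double> n(counts.begin(), counts.end());
  std::vector<double> a(net->nch);
  calc_prop(*net, n, V, surface_of(*net, n), stoch, a);
  return NumericVector(a.begin(), a.end());
}

// Deterministic RHS: y = (counts, V_C); returns dy/dt. `mask` marks the
// species reachable from the initial support: unreachable species live in
// an invariant zero subspace, but the stiff solver injects local-error
// noise there which autocatalytic replication would amplify; masking pins
// them (value read as 0, derivative 0).
// [[Rcpp::export]]
NumericVector rc_det_rhs(SEXP xp, NumericVector y, IntegerVector mask) {
  XPtr<Net> net(xp);
  const int nsp = net->nsp;
  std::vector<double> n(y.begin(), y.begin() + nsp);
  for (int i = 0; i < nsp; ++i) if (!mask[i]) n[i] = 0.0;
  double V = y[nsp];
  double S = surface_of(*net, n);
  std::vector<double> a(net->nch);
  calc_prop(*net, n, V, S, false, a);
  NumericVector dy(nsp + 1);
  for (int j = 0; j < net->nch; ++j) {
    if (a[j] == 0) continue;
    for (int p = net->sptr[j]; p < net->sptr[j + 1]; ++p)
      dy[net->sidx[p]] += net->sdel[p] * a[j];
  }
  for (int i = 0; i < nsp; ++i) if (!mask[i]) dy[i] = 0.0;
  double CTC = osm_sum(*net, n) / (V * net->NAv);
  dy[nsp] = net->v_aq * net->P_aq * S * (CTC - net->C_T_E);
  return dy;
}

// One SSA episode: runs from t0 until division, burst, or t_max.
// fate: 0 timeout, 1 divide, 2 burst, 3 step-limit.
// [[Rcpp::export]]
List rc_ssa(SEXP xp, NumericVector counts0, double t0, double t_max,
            bool hybrid, double threshold, double eps_leap, double g_min,
            double dt_max, double record_dt, double max_steps) {
  XPtr<Net> net(xp);
  const int nsp = net->nsp, nch = net->nch;
  std::vector<double> n(counts0.begin(), counts0.end());
  std::vector<double> a(nch), mu(nsp), var(nsp), nsave(nsp);
  std::vector<char> isleap(nch);

  double osum = osm_sum(*net, n);
  double V = osum / (net->NAv * net->C_T_E);
  double t = t0;
  int fate = 0;
  double steps_exact = 0, steps_leap = 0;
  double E = R::rexp(1.0), Lam = 0;  // hazard for slow set (hybrid)
  double next_rec = (record_dt > 0) ? t0 : R_PosInf;
  std::vector<double> rec;  // rows of (t, V, S, phi)

  while (t < t_max) {
    if (steps_exact + steps_leap > max_steps) { fate = 3; break; }
    double S = surface_of(*net, n);
    double phi = phi_of(S, V);
    if (record_dt > 0) {
      while (next_rec <= t) {
        rec.push_back(next_rec); rec.push_back(V); rec.push_back(S);
        rec.push_back(phi);
        next_rec += record_dt;
      }
    }
    calc_prop(*net, n, V, S, true, a);

    if (!hybrid) {
      double a0 = 0;
      for (int j = 0; j < nch; ++j) a0 += a[j];
      if (a0 <= 0) { t = t_max; break; }
      double tau = R::rexp(1.0 / a0);
      if (t + tau >= t_max) { t = t_max; break; }
      t += tau;
      double r = R::unif_rand() * a0, c = 0;
      int j = nch - 1;
      for (int q = 0; q < nch; ++q) { c += a[q]; if (r <= c) { j = q; break; } }
      apply_channel(*net, j, 1.0, n, false);
      osum = osm_sum(*net, n);
      V = osum / (net->NAv * net->C_T_E);
      steps_exact += 1;
    } else {
      // --- hybrid: leap fast channels, hazard-track the slow set ---
      bool qss = false;
      for (int j = 0; j < nch; ++j)
        isleap[j] = (net->leap[j] && a[j] > threshold) ? 1 : 0;
      if (net->iUpInt >= 0 && isleap[net->iUpInt] && isleap[net->iRelInt]) {
        // Quasi-steady internal aqueous lipid: the release/uptake pair
        // churns at ~1e4 events/s against a pool of ~20 molecules, with
        // fluctuations of the membrane count bounded by the pool size.
        // Sampling the two channels independently would turn that bounded
        // churn into an unbounded random walk, so instead the pool is held
        // at its QSS value (production = release + synthesis balances
        // uptake), the pair is not sampled, and the net effect — every
        // synthesised lipid ends up in the membrane — is applied by
        // re-routing the synthesis product to the membrane.
        qss = true;
        double inflow = a[net->iRelInt];
        if (net->iSynth >= 0) inflow += a[net->iSynth];
        double kup = net->k_in * S / (V * net->NAv);
        n[net->iLaq] = (kup > 0) ? inflow / kup : 0.0;
        a[net->iUpInt] = 0.0;
        a[net->iRelInt] = 0.0;
      }
      double a0_slow = 0;
      for (int j = 0; j < nch; ++j) if (!isleap[j]) a0_slow += a[j];

      // Cao-style tau selection over the leap set
      std::fill(mu.begin(), mu.end(), 0.0);
      std::fill(var.begin(), var.end(), 0.0);
      bool any_leap = false;
      for (int j = 0; j < nch; ++j) {
        if (!isleap[j] || a[j] <= 0) continue;
        any_leap = true;
        for (int p = net->sptr[j]; p < net->sptr[j + 1]; ++p) {
          int i = net->sidx[p];
          if (qss && i == net->iLaq) continue;
          mu[i] += net->sdel[p] * a[j];
          var[i] += net->sdel[p] * net->sdel[p] * a[j];
        }
      }
      double dt = std::min(dt_max, t_max - t);
      for (int i = 0; i < nsp; ++i) {
        if (mu[i] == 0 && var[i] == 0) continue;
        // bound the change of abundant species by eps_leap relative; allow
        // sparse pools to move by up to g_min molecules per leap but never
        // more than ~10% of the pool, so near-empty fast pools (where
        // relative propensity staleness would bias the dynamics) keep an
        // effectively one-molecule resolution while moderately filled slow
        // pools are not allowed to throttle month-long spans to ~5 s steps
        double g = std::max(eps_leap * n[i],
                            std::min(g_min, 0.1 * n[i] + 1.0));
        if (mu[i] != 0) dt = std::min(dt, g / std::fabs(mu[i]));
        if (var[i] > 0) dt = std::min(dt, g * g / var[i]);
      }
      if (!any_leap && a0_slow <= 0) { t = t_max; break; }
      bool fire = false;
      if (a0_slow > 0) {
        double need = (E - Lam) / a0_slow;
        if (need <= dt) { dt = std::max(need, 0.0); fire = true; }
      }

      // Poisson leaps, halving dt on (rare) negative excursions
      std::copy(n.begin(), n.end(), nsave.begin());
      int tries = 0;
      for (;;) {
        bool ok = true;
        for (int j = 0; j < nch && ok; ++j) {
          if (!isleap[j] || a[j] <= 0) continue;
          double m = a[j] * dt;
          double kct = (m > 0) ? R::rpois(m) : 0;
          if (kct > 0) {
            apply_channel(*net, j, kct, n, qss);
            if (qss && j == net->iSynth) n[net->iLmem] += kct;
          }
        }
        for (int i = 0; i < nsp; ++i) if (n[i] < 0) { ok = false; break; }
        if (ok) break;
        std::copy(nsave.begin(), nsave.end(), n.begin());
        dt *= 0.5;
        fire = false;  // hazard target no longer reached within dt
        if (++tries > 60) { fate = 3; break; }
      }
      if (fate == 3) break;

      if (fire) {
        double r = R::unif_rand() * a0_slow, c = 0;
        int jf = -1;
        for (int q = 0; q < nch; ++q) {
          if (isleap[q]) continue;
          c += a[q];
          if (r <= c) { jf = q; break; }
        }
        if (jf >= 0) {
          apply_channel(*net, jf, 1.0, n, qss);
          if (qss && jf == net->iSynth) n[net->iLmem] += 1;
        }
        E = R::rexp(1.0); Lam = 0;
      } else {
        Lam += a0_slow * dt;
      }
      t += dt;
      osum = osm_sum(*net, n);
      V = osum / (net->NAv * net->C_T_E);
      steps_leap += 1;
    }

    // stability window
    double S2 = surface_of(*net, n);
    double phi2 = phi_of(S2, V);
    if (phi2 >= net->phi_div) { fate = 1; break; }
    if (phi2 < net->phi_burst) { fate = 2; break; }
  }

  NumericMatrix traj(rec.size() / 4, 4);
  for (int r = 0; r < traj.nrow(); ++r)
    for (int c = 0; c < 4; ++c) traj(r, c) = rec[4 * r + c];
  return List::create(_["fate"] = fate, _["t"] = t,
                      _["counts"] = NumericVector(n.begin(), n.end()),
                      _["V"] = V,
                      _["steps_exact"] = steps_exact,
                      _["steps_leap"] = steps_leap,
                      _["traj"] = traj);
}
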
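// Joint MCMC over per-taxon lifespans (Ts, Te), piecewise-constant
// origination/extinction rates and preservation parameters.
//
// Two samplers share this core: BDCS (shift times fixed at stage
// boundaries) and RJMCMC (trans-dimensional moves on the number and
// placement of shifts, independently for origination and extinction).
// Rates are Gibbs-updated through gamma conjugacy; lifespans move by
// reflected sliding-window Metropolis steps; preservation rates are
// conjugate given per-taxon gamma-category indicators.
//
// Time is Ma before present (larger = older); rate step functions store
// descending edge vectors [t_old, shifts..., t_young].

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct StepFun {
  std::vector<double> edges;  // size k+2, descending
  std::vector<double> val;    // size k+1
  std::vector<double> cum;    // cum[j] = integral from edges[j] up to edges[0]

  void rebuild() {
    cum.assign(edges.size(), 0.0);
    for (size_t j = 1; j < edges.size(); ++j)
      cum[j] = cum[j - 1] + val[j - 1] * (edges[j - 1] - edges[j]);
  }
  int interval(double t) const {
    int j = 0, k = (int)val.size();
    while (j < k - 1 && t <= edges[j + 1]) ++j;
    return j;
  }
  double value(double t) const { return val[interval(t)]; }
  // integral of the rate from t up to edges[0] (t clamped to support)
  double cum_at(double t) const {
    if (t >= edges.front()) return 0.0;
    if (t <= edges.back()) return cum.back();
    int j = interval(t);
    return cum[j] + val[j] * (edges[j] - t);
  }
  // integral over [lo, hi] (ages, hi older)
  double integral(double lo, double hi) const {
    return cum_at(lo) - cum_at(hi);
  }
};

// exact fold of x into [lo, hi] by repeated boundary reflection
static double reflect(double x, double lo, double hi) {
  double w = hi - lo;
  if (w <= 0.0) return lo;
  double p = 2.0 * w;
  double y = x - lo;
  y -= p * std::floor(y / p);
  if (y > w) y = 2.0 * w - y;
  return lo + y;
}

// mean-one discretised gamma multipliers (equal-probability category means)
static std::vector<double> gamma_cats(double alpha, int K) {
  std::vector<double> m(K, 1.0);
  if (K <= 1) return m;
  for (int k = 0; k < K; ++k) {
    double lo = (k == 0) ? 0.0 : R::qgamma((double)k / K, alpha, 1.0 / alpha, 1, 0);
    double hi = (k == K - 1) ? R_PosInf
                             : R::qgamma((double)(k + 1) / K, alpha, 1.0 / alpha, 1, 0);
    double plo = R::pgamma(lo, alpha + 1.0, 1.0 / alpha, 1, 0);
    double phi = (k == K - 1) ? 1.0 : R::pgamma(hi, alpha + 1.0, 1.0 / alpha, 1, 0);
    m[k] = K * (phi - plo);
  }
  return m;
}

struct Sampler {
  // data
  int n;
  std::vector<std::vector<double>> occ;  // sorted decreasing
  std::vector<double> first_occ, last_occ;
  std::vector<int> nocc;
  std::vector<bool> extant;
  double t_old, t_young;

  // model switches
  int model;       // 0 = BDCS, 1 = RJMCMC
  int pres_kind;   // 0 = HPP, 1 = TPP, 2 = NHPP
  bool gamma_het;
  int K;
  double beta_shape;
  bool prior_only;

  // priors / constraints
  double q_shape, hyp_rate, rate_prior, nu_shift, min_dt, edge_old, edge_young;
  double d_tste, d_move;
  bool condition;  // condition each observed taxon on >= 1 occurrence
  bool augment;    // data-augment entirely unobserved lineages
  double p_ext;    // proposal probability of an extant augmented lineage

  // augmented (zero-occurrence) lineages
  std::vector<double> aug_ts, aug_te;
  std::vector<bool> aug_extant;
  std::vector<int> aug_cat;

  // state
  std::vector<double> ts, te;
  StepFun lam, mu;
  std::vector<double> pres_edges;  // TPP bins (descending)
  std::vector<double> qv;          // length 1 (HPP/NHPP) or n pres bins
  std::vector<double> qcum;        // TPP cumulative integral
  double alpha, r_q;
  std::vector<int> cat;
  std::vector<double> mult;        // current category multipliers per taxon
  std::vector<double> catval;      // multipliers per category
  std::vector<int> nb;             // TPP occurrences per pres bin (fixed)
  int n_occ_total;

  void rebuild_qcum() {
    qcum.assign(pres_edges.size(), 0.0);
    for (size_t j = 1; j < pres_edges.size(); ++j)
      qcum[j] = qcum[j - 1] + qv[j - 1] * (pres_edges[j - 1] - pres_edges[j]);
  }
  double qcum_at(double t) const {
    if (t >= pres_edges.front()) return 0.0;
    if (t <= pres_edges.back()) return qcum.back();
    size_t j = 0;
    while (j < qv.size() - 1 && t <= pres_edges[j + 1]) ++j;
    return qcum[j] + qv[j] * (pres_edges[j] - t);
  }
  double qint(double lo, double hi) const { return qcum_at(lo) - qcum_at(hi); }

  double sumlogf(int i, double tsi, double tei) const {
    double L = tsi - tei, s = 0.0;
    if (L <= 0.0) return R_NegInf;
    for (double a : occ[i]) {
      double v = (tsi - a) / L;
      s += R::dbeta(v, beta_shape, beta_shape, 1);
    }
    return s;
  }

  // preservation integral factor of taxon i (multiplied by mult[i])
  double pres_int(int i, double tsi, double tei) const {
    if (pres_kind == 1) return qint(tei, tsi);
    return qv[0] * (tsi - tei);
  }

  // -log P(>= 1 occurrence) given integrated intensity A (detection
  // conditioning for observed taxa)
  double det_corr(double A) const {
    if (!condition) return 0.0;
    return -std::log1p(-std::exp(-A));
  }

  void update_lifespans() {
    for (int i = 0; i < n; ++i) {
      // --- Ts ---
      double lo = first_occ[i], hi = t_old;
      if (hi > lo) {
        double prop = reflect(ts[i] + R::runif(-d_tste, d_tste), lo, hi);
        if (prop > lo) {
          double A0 = mult[i] * pres_int(i, ts[i], te[i]);
          double A1 = mult[i] * pres_int(i, prop, te[i]);
          double d = -(A1 - A0) + det_corr(A1) - det_corr(A0);
          if (pres_kind == 2)
            d += sumlogf(i, prop, te[i]) - sumlogf(i, ts[i], te[i]);
          d += std::log(lam.value(prop)) - std::log(lam.value(ts[i]));
          d -= (lam.integral(te[i], prop) + mu.integral(te[i], prop)) -
               (lam.integral(te[i], ts[i]) + mu.integral(te[i], ts[i]));
          if (std::log(R::runif(0.0, 1.0)) < d) ts[i] = prop;
        }
      }
      // --- Te ---
      if (!extant[i]) {
        double lo2 = t_young, hi2 = last_occ[i];
        if (hi2 > lo2) {
          double prop = reflect(te[i] + R::runif(-d_tste, d_tste), lo2, hi2);
          if (prop < hi2) {
            double A0 = mult[i] * pres_int(i, ts[i], te[i]);
            double A1 = mult[i] * pres_int(i, ts[i], prop);
            double d = -(A1 - A0) + det_corr(A1) - det_corr(A0);
            if (pres_kind == 2)
              d += sumlogf(i, ts[i], prop) - sumlogf(i, ts[i], te[i]);
            d += std::log(mu.value(prop)) - std::log(mu.value(te[i]));
            d -= (lam.integral(prop, ts[i]) + mu.integral(prop, ts[i])) -
                 (lam.integral(te[i], ts[i]) + mu.integral(te[i], ts[i]));
            if (std::log(R::runif(0.0, 1.0)) < d) te[i] = prop;
          }
        }
      }
    }
  }

  // events for a rate: origination times (lambda) or extinction times of
  // extinct taxa (mu); augmented lineages count like observed ones
  void event_times(bool is_lambda, std::vector<double> &ev) const {
    ev.clear();
    for (int i = 0; i < n; ++i) {
      if (is_lambda) ev.push_back(ts[i]);
      else if (!extant[i]) ev.push_back(te[i]);
    }
    for (size_t a = 0; a < aug_ts.size(); ++a) {
      if (is_lambda) ev.push_back(aug_ts[a]);
      else if (!aug_extant[a]) ev.push_back(aug_te[a]);
    }
  }

  void add_exposure(const StepFun &f, double tsi, double tei,
                    std::vector<double> &T) const {
    int ja = f.interval(tsi), jb = f.interval(tei);
    for (int j = ja; j <= jb; ++j) {
      double hi = std::min(tsi, f.edges[j]);
      double lo = std::max(tei, f.edges[j + 1]);
      if (hi > lo) T[j] += hi - lo;
    }
  }

  void interval_stats(const StepFun &f, const std::vector<double> &ev,
                      std::vector<int> &B, std::vector<double> &T) const {
    int k = (int)f.val.size();
    B.assign(k, 0);
    T.assign(k, 0.0);
    if (prior_only) return;
    for (double e : ev) B[f.interval(e)]++;
    for (int i = 0; i < n; ++i) add_exposure(f, ts[i], te[i], T);
    for (size_t a = 0; a < aug_ts.size(); ++a)
      add_exposure(f, aug_ts[a], aug_te[a], T);
  }

  void gibbs_rates(StepFun &f, bool is_lambda) {
    std::vector<double> ev;
    event_times(is_lambda, ev);
    std::vector<int> B;
    std::vector<double> T;
    interval_stats(f, ev, B, T);
    for (size_t j = 0; j < f.val.size(); ++j)
      f.val[j] = R::rgamma(B[j] + 1.0, 1.0 / (T[j] + rate_prior));
    f.rebuild();
  }

  // events / lineage time within an age band (lo, hi]
  void band_stats(const std::vector<double> &ev, double lo, double hi,
                  int &B, double &T) const {
    B = 0;
    T = 0.0;
    if (prior_only) return;
    for (double e : ev)
      if (e > lo && e <= hi) ++B;
    for (int i = 0; i < n; ++i) {
      double a = std::max(te[i], lo), b = std::min(ts[i], hi);
      if (b > a) T += b - a;
    }
    for (size_t x = 0; x < aug_ts.size(); ++x) {
      double a = std::max(aug_te[x], lo), b = std::min(aug_ts[x], hi);
      if (b > a) T += b - a;
    }
  }

  bool min_dt_ok(const StepFun &f, double tstar, int skip = -1) const {
    int k = (int)f.val.size() - 1;  // number of interior shifts
    for (int m = 1; m <= k; ++m) {
      if (m == skip) continue;
      if (std::fabs(f.edges[m] - tstar) < min_dt) return false;
    }
    return true;
  }

  void rj_update(StepFun &f, bool is_lambda) {
    std::vector<double> ev;
    event_times(is_lambda, ev);
    int k = (int)f.val.size() - 1;  // current shift count
    double u3 = R::runif(0.0, 1.0);
    if (u3 < 1.0 / 3.0) {  // birth
      double tstar = R::runif(edge_young, edge_old);
      if (!min_dt_ok(f, tstar)) return;
      int j = f.interval(tstar);
      double s1 = f.edges[j] - tstar, s2 = tstar - f.edges[j + 1];
      if (s1 <= 0.0 || s2 <= 0.0) return;
      double u = R::runif(0.0, 1.0);
      double z = std::log(u / (1.0 - u));
      double l = f.val[j];
      double l1 = l * std::exp(s2 / (s1 + s2) * z);
      double l2 = l * std::exp(-s1 / (s1 + s2) * z);
      int B1, B2;
      double T1, T2;
      band_stats(ev, tstar, f.edges[j], B1, T1);
      band_stats(ev, f.edges[j + 1], tstar, B2, T2);
      double dL = B1 * std::log(l1) + B2 * std::log(l2) -
                  (B1 + B2) * std::log(l) - (l1 - l) * T1 - (l2 - l) * T2;
      double la = dL + std::log(nu_shift) - std::log((double)k + 1.0) +
                  std::log(rate_prior) - rate_prior * (l1 + l2 - l) +
                  std::log(l1 * l2 / (l * u * (1.0 - u)));
      if (std::log(R::runif(0.0, 1.0)) < la) {
        f.edges.insert(f.edges.begin() + j + 1, tstar);
        f.val[j] = l1;
        f.val.insert(f.val.begin() + j + 1, l2);
        f.rebuild();
      }
    } else if (u3 < 2.0 / 3.0) {  // death
      if (k < 1) return;
      int m = 1 + (int)std::floor(R::runif(0.0, 1.0) * k);
      if (m > k) m = k;
      double s1 = f.edges[m - 1] - f.edges[m], s2 = f.edges[m] - f.edges[m + 1];
      double l1 = f.val[m - 1], l2 = f.val[m];
      double l = std::exp((s1 * std::log(l1) + s2 * std::log(l2)) / (s1 + s2));
      double z = std::log(l1 / l2);
      double u = 1.0 / (1.0 + std::exp(-z));
      int B1, B2;
      double T1, T2;
      band_stats(ev, f.edges[m], f.edges[m - 1], B1, T1);
      band_stats(ev, f.edges[m + 1], f.edges[m], B2, T2);
      double dL = (B1 + B2) * std::log(l) - B1 * std::log(l1) -
                  B2 * std::log(l2) - (l - l1) * T1 - (l - l2) * T2;
      double la = dL - (std::log(nu_shift) - std::log((double)k) +
                        std::log(rate_prior) - rate_prior * (l1 + l2 - l) +
                        std::log(l1 * l2 / (l * u * (1.0 - u))));
      if (std::log(R::runif(0.0, 1.0)) < la) {
        f.edges.erase(f.edges.begin() + m);
        f.val[m - 1] = l;
        f.val.erase(f.val.begin() + m);
        f.rebuild();
      }
    } else {  // move one shift
      if (k < 1) return;
      int m = 1 + (int)std::floor(R::runif(0.0, 1.0) * k);
      if (m > k) m = k;
      double told = f.edges[m];
      double tnew = told + R::rnorm(0.0, d_move);
      if (tnew >= f.edges[m - 1] || tnew <= f.edges[m + 1]) return;
      if (tnew > edge_old || tnew < edge_young) return;
      if (!min_dt_ok(f, tnew, m)) return;
      double dL;
      int Bb;
      double Tb;
      if (tnew < told) {  // older interval (rate val[m-1]) expands
        band_stats(ev, tnew, told, Bb, Tb);
        dL = Bb * (std::log(f.val[m - 1]) - std::log(f.val[m])) -
             (f.val[m - 1] - f.val[m]) * Tb;
      } else {            // younger interval (rate val[m]) expands
        band_stats(ev, told, tnew, Bb, Tb);
        dL = Bb * (std::log(f.val[m]) - std::log(f.val[m - 1])) -
             (f.val[m] - f.val[m - 1]) * Tb;
      }
      if (std::log(R::runif(0.0, 1.0)) < dL) {
        f.edges[m] = tnew;
        f.rebuild();
      }
    }
  }

  // lineages alive strictly spanning time t (potential parents of a birth
  // at t), excluding a lineage born exactly at t
  int n_alive(double t) const {
    int c = 0;
    for (int i = 0; i < n; ++i)
      if (ts[i] > t && te[i] < t) ++c;
    for (size_t x = 0; x < aug_ts.size(); ++x)
      if (aug_ts[x] > t && aug_te[x] < t) ++c;
    return c;
  }

  // complete-data weight of one augmented (never-fossilised) lineage:
  // origination intensity lambda(Ts) x (number of possible parents),
  // birth-death density over the lifespan, times the probability of zero
  // occurrences. Second-order changes to the parent factors of other
  // origination events are O(1/N) and neglected.
  double aug_weight(double tsi, double tei, bool ext, int cat_k,
                    bool clamp_parents = false) const {
    int N = n_alive(tsi);
    if (N < 1) {
      // a later lifespan move can orphan a phantom; the neglected
      // parent-factor cross terms make this state reachable, so clamp
      // when scoring rather than report -Inf
      if (!clamp_parents) return R_NegInf;
      N = 1;
    }
    double w = std::log(lam.value(tsi)) + std::log((double)N);
    if (!ext) w += std::log(mu.value(tei));
    w -= lam.integral(tei, tsi) + mu.integral(tei, tsi);
    w -= catval[cat_k] * pres_int(0, tsi, tei);
    return w;  // log scale
  }

  // spatial birth-death Metropolis-Hastings over the augmented set
  void aug_update() {
    double Wt = t_old - t_young;
    int attempts = std::max(10, n / 5);
    for (int a = 0; a < attempts; ++a) {
      int k = (int)aug_ts.size();
      if (R::runif(0.0, 1.0) < 0.5) {  // birth
        double tsp = R::runif(t_young, t_old);
        bool ext = R::runif(0.0, 1.0) < p_ext;
        double tep, logg;
        if (ext) {
          tep = t_young;
          logg = std::log(p_ext / Wt);
        } else {
          tep = R::runif(t_young, tsp);
          logg = std::log((1.0 - p_ext) / (Wt * (tsp - t_young)));
        }
        int ck = (int)std::floor(R::runif(0.0, 1.0) * K);
        if (ck >= K) ck = K - 1;
        double la = aug_weight(tsp, tep, ext, ck) - logg -
                    std::log((double)k + 1.0);
        if (std::log(R::runif(0.0, 1.0)) < la) {
          aug_ts.push_back(tsp);
          aug_te.push_back(tep);
          aug_extant.push_back(ext);
          aug_cat.push_back(ck);
        }
      } else {  // death
        if (k < 1) continue;
        int j = (int)std::floor(R::runif(0.0, 1.0) * k);
        if (j >= k) j = k - 1;
        double logg = aug_extant[j]
            ? std::log(p_ext / Wt)
            : std::log((1.0 - p_ext) / (Wt * (aug_ts[j] - t_young)));
        double la = logg + std::log((double)k) -
                    aug_weight(aug_ts[j], aug_te[j], aug_extant[j], aug_cat[j]);
        if (std::log(R::runif(0.0, 1.0)) < la) {
          aug_ts.erase(aug_ts.begin() + j);
          aug_te.erase(aug_te.begin() + j);
          aug_extant.erase(aug_extant.begin() + j);
          aug_cat.erase(aug_cat.begin() + j);
        }
      }
    }
  }

  void gibbs_categories() {
    std::vector<double> logw(K);
    for (int i = 0; i < n; ++i) {
      double A = prior_only ? 0.0 : pres_int(i, ts[i], te[i]);
      double mx = R_NegInf;
      for (int kk = 0; kk < K; ++kk) {
        logw[kk] = nocc[i] * std::log(catval[kk]) - catval[kk] * A;
        if (!prior_only) logw[kk] += det_corr(catval[kk] * A);
        if (logw[kk] > mx) mx = logw[kk];
      }
      double tot = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        logw[kk] = std::exp(logw[kk] - mx);
        tot += logw[kk];
      }
      double u = R::runif(0.0, 1.0) * tot, acc = 0.0;
      int pick = K - 1;
      for (int kk = 0; kk < K; ++kk) {
        acc += logw[kk];
        if (u <= acc) { pick = kk; break; }
      }
      cat[i] = pick;
      mult[i] = catval[pick];
    }
    for (size_t x = 0; x < aug_ts.size(); ++x) {
      double A = pres_int(0, aug_ts[x], aug_te[x]);
      double mx = R_NegInf;
      for (int kk = 0; kk < K; ++kk) {
        logw[kk] = -catval[kk] * A;
        if (logw[kk] > mx) mx = logw[kk];
      }
      double tot = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        logw[kk] = std::exp(logw[kk] - mx);
        tot += logw[kk];
      }
      double u = R::runif(0.0, 1.0) * tot, acc = 0.0;
      int pick = K - 1;
      for (int kk = 0; kk < K; ++kk) {
        acc += logw[kk];
        if (u <= acc) { pick = kk; break; }
      }
      aug_cat[x] = pick;
    }
  }

  void mh_alpha() {
    double prop = alpha * std::exp(R::rnorm(0.0, 0.3));
    std::vector<double> mnew = gamma_cats(prop, K);
    double d = 0.0;
    for (int i = 0; i < n; ++i) {
      double A = prior_only ? 0.0 : pres_int(i, ts[i], te[i]);
      double mo = catval[cat[i]], mn = mnew[cat[i]];
      d += nocc[i] * (std::log(mn) - std::log(mo)) - (mn - mo) * A;
      if (!prior_only) d += det_corr(mn * A) - det_corr(mo * A);
    }
    for (size_t x = 0; x < aug_ts.size(); ++x) {
      double A = pres_int(0, aug_ts[x], aug_te[x]);
      d -= (mnew[aug_cat[x]] - catval[aug_cat[x]]) * A;
    }
    d += -0.1 * (prop - alpha) + std::log(prop / alpha);  // Exp(0.1) prior
    if (std::log(R::runif(0.0, 1.0)) < d) {
      alpha = prop;
      catval = mnew;
      for (int i = 0; i < n; ++i) mult[i] = catval[cat[i]];
    }
  }

  // sum over taxa of the detection-conditioning term at the current
  // lifespans, for a given preservation-rate vector
  double corr_sum(const std::vector<double> &q_try) {
    if (!condition || prior_only) return 0.0;
    std::vector<double> save = qv;
    double s = 0.0;
    if (pres_kind == 1) {
      qv = q_try;
      rebuild_qcum();
    }
    for (int i = 0; i < n; ++i) {
      double A = (pres_kind == 1) ? mult[i] * qint(te[i], ts[i])
                                  : q_try[0] * mult[i] * (ts[i] - te[i]);
      s += det_corr(A);
    }
    if (pres_kind == 1) {
      qv = save;
      rebuild_qcum();
    }
    return s;
  }

  // conjugate gamma draw used as an independence proposal; when detection
  // conditioning is on, the proposal is corrected by Metropolis-Hastings
  void gibbs_q() {
    std::vector<double> prop(qv.size());
    if (pres_kind == 1) {
      int Bq = (int)qv.size();
      std::vector<double> S(Bq, 0.0);
      if (!prior_only) {
        for (int i = 0; i < n; ++i) {
          size_t j = 0;
          while (j < qv.size() && pres_edges[j + 1] >= ts[i]) ++j;
          for (; j < qv.size() && pres_edges[j] > te[i]; ++j) {
            double hi = std::min(ts[i], pres_edges[j]);
            double lo = std::max(te[i], pres_edges[j + 1]);
            if (hi > lo) S[j] += mult[i] * (hi - lo);
          }
        }
        for (size_t x = 0; x < aug_ts.size(); ++x) {
          for (size_t j = 0; j < qv.size(); ++j) {
            double hi = std::min(aug_ts[x], pres_edges[j]);
            double lo = std::max(aug_te[x], pres_edges[j + 1]);
            if (hi > lo) S[j] += catval[aug_cat[x]] * (hi - lo);
          }
        }
      }
      for (int b = 0; b < Bq; ++b) {
        double shp = q_shape + (prior_only ? 0.0 : (double)nb[b]);
        prop[b] = R::rgamma(shp, 1.0 / (r_q + S[b]));
      }
    } else {
      double S = 0.0;
      int N = 0;
      if (!prior_only) {
        for (int i = 0; i < n; ++i) S += mult[i] * (ts[i] - te[i]);
        for (size_t x = 0; x < aug_ts.size(); ++x)
          S += catval[aug_cat[x]] * (aug_ts[x] - aug_te[x]);
        N = n_occ_total;
      }
      prop[0] = R::rgamma(q_shape + N, 1.0 / (r_q + S));
    }
    if (!condition || prior_only) {
      qv = prop;
    } else {
      double la = corr_sum(prop) - corr_sum(qv);
      if (std::log(R::runif(0.0, 1.0)) < la) qv = prop;
    }
    if (pres_kind == 1) rebuild_qcum();
    double qsum = 0.0;
    for (double qb : qv) qsum += qb;
    r_q = R::rgamma(1.0 + q_shape * (double)qv.size(),
                    1.0 / (hyp_rate + qsum));
  }

  double total_loglik() const {
    if (prior_only) return 0.0;
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      ll += std::log(lam.value(ts[i]));
      if (!extant[i]) ll += std::log(mu.value(te[i]));
      ll -= lam.integral(te[i], ts[i]) + mu.integral(te[i], ts[i]);
      if (pres_kind == 1) {
        double A = mult[i] * qint(te[i], ts[i]);
        ll += nocc[i] * std::log(mult[i]) - A + det_corr(A);
      } else {
        double A = qv[0] * mult[i] * (ts[i] - te[i]);
        ll += nocc[i] * std::log(qv[0] * mult[i]) - A + det_corr(A);
        if (pres_kind == 2) ll += sumlogf(i, ts[i], te[i]);
      }
    }
    if (pres_kind == 1) {
      for (size_t b = 0; b < qv.size(); ++b)
        if (nb[b] > 0) ll += nb[b] * std::log(qv[b]);
    }
    for (size_t x = 0; x < aug_ts.size(); ++x)
      ll += aug_weight(aug_ts[x], aug_te[x], aug_extant[x], aug_cat[x], true);
    return ll;
  }
};

// [[Rcpp::export]]
List cpp_bdmcmc(List occ_list, LogicalVector extant_in, double t_old,
                double t_young, int model, NumericVector fixed_shifts,
                int pres_kind, NumericVector pres_edges_in, bool gamma_het,
                int K, double beta_shape, double q_shape, double hyp_rate,
                double rate_prior, double nu_shift, double min_dt,
                double edge_old, double edge_young, int n_gen, int thin,
                double d_tste, double d_move, NumericVector grid,
                bool prior_only, bool condition, bool augment) {
  Sampler S;
  S.n = occ_list.size();
  S.t_old = t_old;
  S.t_young = t_young;
  S.model = model;
  S.pres_kind = pres_kind;
  S.gamma_het = gamma_het;
  S.K = gamma_het ? K : 1;
  S.beta_shape = beta_shape;
  S.prior_only = prior_only;
  S.q_shape = q_shape;
  S.hyp_rate = hyp_rate;
  S.rate_prior = rate_prior;
  S.nu_shift = nu_shift;
  S.min_dt = min_dt;
  S.edge_old = std::min(edge_old, t_old);
  S.edge_young = std::max(edge_young, t_young);
  S.d_tste = d_tste;
  S.d_move = d_move;
  S.condition = condition && !augment;
  S.augment = augment;
  S.p_ext = 0.2;

  S.occ.resize(S.n);
  S.first_occ.resize(S.n);
  S.last_occ.resize(S.n);
  S.nocc.resize(S.n);
  S.extant.resize(S.n);
  S.n_occ_total = 0;
  for (int i = 0; i < S.n; ++i) {
    NumericVector a = occ_list[i];
    S.occ[i] = std::vector<double>(a.begin(), a.end());
    std::sort(S.occ[i].begin(), S.occ[i].end(), std::greater<double>());
    S.first_occ[i] = S.occ[i].front();
    S.last_occ[i] = S.occ[i].back();
    S.nocc[i] = (int)S.occ[i].size();
    S.n_occ_total += S.nocc[i];
    S.extant[i] = extant_in[i];
  }

  // initial lifespans
  S.ts.resize(S.n);
  S.te.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    S.ts[i] = std::min(t_old, S.first_occ[i] + 0.25 * (t_old - S.first_occ[i]));
    if (S.ts[i] <= S.first_occ[i]) S.ts[i] = t_old;
    if (S.extant[i] || S.last_occ[i] <= t_young) {
      S.te[i] = t_young;
      S.extant[i] = S.extant[i] || S.last_occ[i] <= t_young;
    } else {
      S.te[i] = S.last_occ[i] - 0.25 * (S.last_occ[i] - t_young);
    }
  }

  // rate step functions
  std::vector<double> edges;
  edges.push_back(t_old);
  if (model == 0)
    for (double s : fixed_shifts)
      if (s < t_old && s > t_young) edges.push_back(s);
  edges.push_back(t_young);
  S.lam.edges = edges;
  S.lam.val.assign(edges.size() - 1, 0.1);
  S.lam.rebuild();
  S.mu = S.lam;

  // preservation
  if (pres_kind == 1) {
    S.pres_edges = std::vector<double>(pres_edges_in.begin(), pres_edges_in.end());
    S.qv.assign(S.pres_edges.size() - 1, 1.0);
    S.nb.assign(S.qv.size(), 0);
    for (int i = 0; i < S.n; ++i)
      for (double a : S.occ[i]) {
        size_t j = 0;
        while (j < S.qv.size() - 1 && a <= S.pres_edges[j + 1]) ++j;
        S.nb[j]++;
      }
    S.rebuild_qcum();
  } else {
    S.pres_edges = {t_old, t_young};
    S.qv.assign(1, 1.0);
    S.nb.assign(1, S.n_occ_total);
  }
  S.alpha = 1.0;
  S.r_q = 1.0;
  S.catval = gamma_cats(S.alpha, S.K);
  S.cat.assign(S.n, 0);
  S.mult.assign(S.n, 1.0);

  int n_samp = n_gen / thin;
  int Gg = grid.size();
  NumericMatrix lam_out(n_samp, Gg), mu_out(n_samp, Gg);
  NumericMatrix ts_out(n_samp, S.n), te_out(n_samp, S.n);
  NumericMatrix q_out(n_samp, S.qv.size());
  NumericVector alpha_out(n_samp), ll_out(n_samp);
  IntegerVector kl_out(n_samp), km_out(n_samp), naug_out(n_samp);
  std::vector<double> shl_t, shm_t;
  std::vector<int> shl_s, shm_s;

  int rec = 0;
  for (int g = 1; g <= n_gen; ++g) {
    if (!prior_only) S.update_lifespans();
    if (S.augment && !prior_only) S.aug_update();
    S.gibbs_rates(S.lam, true);
    S.gibbs_rates(S.mu, false);
    if (model == 1) {
      S.rj_update(S.lam, true);
      S.rj_update(S.mu, false);
    }
    if (gamma_het) {
      S.gibbs_categories();
      S.mh_alpha();
    }
    S.gibbs_q();

    if (g % thin == 0 && rec < n_samp) {
      for (int j = 0; j < Gg; ++j) {
        lam_out(rec, j) = S.lam.value(grid[j]);
        mu_out(rec, j) = S.mu.value(grid[j]);
      }
      for (int i = 0; i < S.n; ++i) {
        ts_out(rec, i) = S.ts[i];
        te_out(rec, i) = S.te[i];
      }
      for (size_t b = 0; b < S.qv.size(); ++b) q_out(rec, b) = S.qv[b];
      alpha_out[rec] = S.alpha;
      ll_out[rec] = S.total_loglik();
      kl_out[rec] = (int)S.lam.val.size() - 1;
      km_out[rec] = (int)S.mu.val.size() - 1;
      naug_out[rec] = (int)S.aug_ts.size();
      for (size_t m = 1; m + 1 < S.lam.edges.size(); ++m) {
        shl_t.push_back(S.lam.edges[m]);
        shl_s.push_back(rec + 1);
      }
      for (size_t m = 1; m + 1 < S.mu.edges.size(); ++m) {
        shm_t.push_back(S.mu.edges[m]);
        shm_s.push_back(rec + 1);
      }
      ++rec;
    }
    if (g % 5000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["lambda"] = lam_out, _["mu"] = mu_out, _["ts"] = ts_out,
      _["te"] = te_out, _["q"] = q_out, _["alpha"] = alpha_out,
      _["loglik"] = ll_out, _["k_lambda"] = kl_out, _["k_mu"] = km_out,
      _["n_aug"] = naug_out,
      _["shift_lambda"] = DataFrame::create(_["sample"] = shl_s, _["time"] = shl_t),
      _["shift_mu"] = DataFrame::create(_["sample"] = shm_s, _["time"] = shm_t),
      _["n_samples"] = n_samp);
}
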
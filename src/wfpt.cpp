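// Wiener diffusion first-passage numerics for the two-boundary drift
// diffusion model used throughout the package.
//
// Conventions (fixed package-wide):
//   * lower boundary 0  = cooperate, upper boundary a = defect;
//   * z in (0,1) is the prosocial (cooperation-ward) starting-point bias,
//     the accumulator starts at a*(1-z);
//   * drift v pushes toward the defection boundary; s is the diffusion
//     noise scale.  All formulas are evaluated after rescaling by s
//     (a/s, v/s), which leaves choice/RT distributions unchanged.
//
// Densities use the standard small-time / large-time series pair with the
// truncation rule that picks, for a target series error, whichever
// expansion needs fewer terms (the classic crossover rule).  CDFs use the
// term-by-term integrated large-time series, which converges for all t>0;
// partial sums are clamped into [0, P(boundary)].

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static const double PI_ = 3.141592653589793238462643383280;

// ---------------------------------------------------------------------------
// closed-form absorption probability at the upper (defect) boundary
// ---------------------------------------------------------------------------

static double p_upper_impl(double v, double a, double z, double s) {
  const double av = a / s, vv = v / s;
  const double x = 2.0 * vv * av;              // exponent scale
  if (std::fabs(x) < 1e-10) return 1.0 - z;    // driftless limit
  // P(hit a | start a*(1-z)) = (1 - exp(-2 v a (1-z)/s^2)) / (1 - exp(-2 v a/s^2))
  return std::expm1(-x * (1.0 - z)) / std::expm1(-x);
}

// ---------------------------------------------------------------------------
// f0: density of first passage at the LOWER boundary for unit boundary,
// zero drift, start fraction w, unit noise, at scaled time tau.
// Small-time and large-time series with error-targeted truncation.
// ---------------------------------------------------------------------------

static double f0_lower(double tau, double w, double err) {
  if (tau <= 0.0) return 0.0;
  // terms needed by each expansion (crossover rule, target error `err`)
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * PI_ * tau) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tau * std::log(2.0 * err * std::sqrt(2.0 * PI_ * tau)));
    ks = std::max(ks, std::sqrt(tau) + 1.0);
  } else {
    ks = 2.0;
  }
  if (PI_ * tau * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(PI_ * tau * err) / (PI_ * PI_ * tau));
    kl = std::max(kl, 1.0 / (PI_ * std::sqrt(tau)));
  } else {
    kl = 1.0 / (PI_ * std::sqrt(tau));
  }
  double p = 0.0;
  if (ks < kl) {                                // small-time expansion
    const int K = (int)std::ceil(ks);
    for (int k = -K; k <= K; ++k) {
      const double u = w + 2.0 * k;
      p += u * std::exp(-u * u / (2.0 * tau));
    }
    p /= std::sqrt(2.0 * PI_ * tau * tau * tau);
  } else {                                      // large-time expansion
    const int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-k * k * PI_ * PI_ * tau / 2.0) * std::sin(k * PI_ * w);
    }
    p *= PI_;
  }
  return std::max(p, 0.0);
}

// defective density of first passage at the lower boundary, general drift.
// (vv, av already rescaled by s; w = start fraction from the lower boundary)
static double dens_lower(double t, double vv, double av, double w, double err) {
  if (t <= 0.0) return 0.0;
  const double tau = t / (av * av);
  const double pref = std::exp(-vv * av * w - vv * vv * t / 2.0) / (av * av);
  return pref * f0_lower(tau, w, err);
}

// CDF of first passage at the lower boundary (defective), via the
// analytically integrated large-time series: F(t) = P_lower - tail(t).
static double cdf_lower(double t, double vv, double av, double w, double s_unused) {
  (void)s_unused;
  if (t <= 0.0) return 0.0;
  // P(hit lower) = 1 - P(hit upper with start fraction w from lower)
  double p_low;
  {
    const double x = 2.0 * vv * av;
    if (std::fabs(x) < 1e-10) p_low = 1.0 - w;
    else p_low = 1.0 - std::expm1(-x * w) / std::expm1(-x);
  }
  const double pref = (PI_ / (av * av)) * std::exp(-vv * av * w);
  double tail = 0.0;
  const int KMAX = 50000;
  for (int k = 1; k <= KMAX; ++k) {
    const double lam = 0.5 * (vv * vv + k * k * PI_ * PI_ / (av * av));
    const double env = pref * k / lam * std::exp(-lam * t);  // |term| bound
    if (env < 1e-13 && k > 2) break;
    tail += pref * k * std::sin(k * PI_ * w) / lam * std::exp(-lam * t);
  }
  double F = p_low - tail;
  if (F < 0.0) F = 0.0;
  if (F > p_low) F = p_low;
  return F;
}

// helpers mapping the package (v, a, z, s) convention onto the lower-boundary
// primitives: defect = upper boundary = lower boundary of the sign-flipped
// process with start fraction z.
static inline double dens_boundary(double t, double v, double a, double z,
                                   double s, bool upper, double err) {
  const double av = a / s, vv = v / s;
  return upper ? dens_lower(t, -vv, av, z, err)
               : dens_lower(t,  vv, av, 1.0 - z, err);
}

static inline double cdf_boundary(double t, double v, double a, double z,
                                  double s, bool upper) {
  const double av = a / s, vv = v / s;
  return upper ? cdf_lower(t, -vv, av, z, 0.0)
               : cdf_lower(t,  vv, av, 1.0 - z, 0.0);
}

// [[Rcpp::export]]
double cpp_choice_prob(double v, double a, double z, double s) {
  return p_upper_impl(v, a, z, s);
}

// [[Rcpp::export]]
NumericVector cpp_fpt_density(NumericVector t, double v, double a, double z,
                              double s, bool upper, double err) {
  const int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = dens_boundary(t[i], v, a, z, s, upper, err);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fpt_cdf(NumericVector t, double v, double a, double z,
                          double s, bool upper) {
  const int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = cdf_boundary(t[i], v, a, z, s, upper);
  return out;
}

// conditional decision-time quantile at the named boundary (no t_er shift);
// bisection on the defective CDF divided by the boundary probability.
static double quantile_one(double p, double v, double a, double z, double s,
                           bool upper) {
  const double pb = upper ? p_upper_impl(v, a, z, s)
                          : 1.0 - p_upper_impl(v, a, z, s);
  const double target = p * pb;
  double hi = 1.0;
  while (cdf_boundary(hi, v, a, z, s, upper) < target && hi < 1e6) hi *= 2.0;
  double lo = 0.0;
  for (int it = 0; it < 200; ++it) {
    const double mid = 0.5 * (lo + hi);
    if (cdf_boundary(mid, v, a, z, s, upper) < target) lo = mid; else hi = mid;
    if (hi - lo < 1e-12 * (1.0 + hi)) break;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
NumericVector cpp_fpt_quantile(NumericVector probs, double v, double a,
                               double z, double s, bool upper) {
  const int n = probs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = quantile_one(probs[i], v, a, z, s, upper);
  return out;
}

// ---------------------------------------------------------------------------
// Euler-Maruyama trial simulator (seeded, deterministic per seed)
// ---------------------------------------------------------------------------

// xoshiro256++ with splitmix64 seeding and a polar Box-Muller normal:
// substantially faster than std::normal_distribution over mt19937_64,
// which dominates the cost of small-step Euler simulation.
struct FastNormal {
  uint64_t st[4];
  double cached;
  bool has_cached;
  explicit FastNormal(uint64_t seed) : has_cached(false) {
    for (int i = 0; i < 4; ++i) {           // splitmix64 expansion
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t x = seed;
      x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
      x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
      st[i] = x ^ (x >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next_u64() {
    const uint64_t result = rotl(st[0] + st[3], 23) + st[0];
    const uint64_t t = st[1] << 17;
    st[2] ^= st[0]; st[3] ^= st[1]; st[1] ^= st[2]; st[0] ^= st[3];
    st[2] ^= t; st[3] = rotl(st[3], 45);
    return result;
  }
  inline double next_unif() {               // (-1, 1)
    return (double)((int64_t)next_u64() >> 11) * (1.0 / 4503599627370496.0);
  }
  inline double next_unif01() {             // [0, 1)
    return (double)(next_u64() >> 11) * (1.0 / 9007199254740992.0);
  }
  inline double next_norm() {
    if (has_cached) { has_cached = false; return cached; }
    double u, w, r2;
    do {
      u = next_unif();
      w = next_unif();
      r2 = u * u + w * w;
    } while (r2 >= 1.0 || r2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(r2) / r2);
    cached = w * f;
    has_cached = true;
    return u * f;
  }
};

// [[Rcpp::export]]
List cpp_simulate(int n, double v, double a, double z, double s, double ter,
                  double dt, double seed) {
  FastNormal rng((uint64_t)seed);
  const double sd = s * std::sqrt(dt);
  const double x0 = a * (1.0 - z);
  const long max_steps = (long)std::ceil(120.0 / dt);  // 2-minute hard cap
  IntegerVector choice(n);
  NumericVector rt(n);
  // Brownian-bridge mid-step crossing test: a discrete walk that stays
  // inside the boundaries may still have crossed between grid points;
  // ignoring this biases absorption probabilities and first-passage
  // times by O(sqrt(dt)).  The bridge crossing probability for a
  // boundary at distance d1 (before) and d2 (after) is
  // exp(-2 d1 d2 / (s^2 dt)); the test is skipped when the exponent is
  // below e^-20.
  const double s2dt = s * s * dt;
  const double bridge_cut = 10.0 * s2dt;
  for (int i = 0; i < n; ++i) {
    double x = x0;
    long k = 0;
    int hit = -1;
    while (k < max_steps) {
      const double x_old = x;
      x += v * dt + sd * rng.next_norm();
      ++k;
      if (x >= a) { hit = 1; break; }
      if (x <= 0.0) { hit = 0; break; }
      const double du = (a - x_old) * (a - x);
      if (du < bridge_cut &&
          rng.next_unif01() < std::exp(-2.0 * du / s2dt)) { hit = 1; break; }
      const double dl = x_old * x;
      if (dl < bridge_cut &&
          rng.next_unif01() < std::exp(-2.0 * dl / s2dt)) { hit = 0; break; }
    }
    if (hit < 0) hit = (x >= a / 2.0) ? 1 : 0;  // censored walk: nearest boundary
    choice[i] = hit;                            // 1 = defect, 0 = cooperate
    rt[i] = k * dt + ter;
  }
  return List::create(_["choice"] = choice, _["rt"] = rt);
}

// ---------------------------------------------------------------------------
// Batched quantile-probability chi-square objective
// ---------------------------------------------------------------------------
//
// Each candidate row holds (v,a,z) for the three conditions plus one shared
// t_er: columns v1,a1,z1,v2,a2,z2,v3,a3,z3,ter.  Observed data arrive as
// per-condition sorted decision RT vectors split by response.  The statistic
// sums, over condition x response, the chi-square distance between observed
// trial counts in the bins cut at the model-predicted RT quantiles (masses
// 0.1, 0.2, 0.2, 0.2, 0.2, 0.1 for the canonical probs) and the expected
// counts, plus a response-proportion cell per response.  Responses with
// fewer than `min_count` observed trials contribute the proportion cell only.

static const int GRID_N = 96;

// conditional decision-time quantiles via a log-spaced CDF grid + linear
// interpolation (fast path used inside the optimizer).
static void grid_quantiles(double v, double a, double z, double s, bool upper,
                           double pb, const std::vector<double>& probs,
                           std::vector<double>& out) {
  const double t_lo = 1e-3, t_hi = 30.0;
  const double lr = std::log(t_hi / t_lo) / (GRID_N - 1);
  double tg[GRID_N], Fg[GRID_N];
  for (int j = 0; j < GRID_N; ++j) {
    tg[j] = t_lo * std::exp(lr * j);
    double F = cdf_boundary(tg[j], v, a, z, s, upper) / std::max(pb, 1e-12);
    if (j > 0 && F < Fg[j - 1]) F = Fg[j - 1];  // enforce monotone
    Fg[j] = F;
  }
  const int np = (int)probs.size();
  out.resize(np);
  int j = 0;
  for (int i = 0; i < np; ++i) {
    const double p = probs[i];
    while (j < GRID_N - 1 && Fg[j + 1] < p) ++j;
    if (Fg[j + 1] <= Fg[j]) { out[i] = tg[j + 1]; continue; }
    if (p <= Fg[0]) { out[i] = tg[0]; continue; }
    const double fr = (p - Fg[j]) / (Fg[j + 1] - Fg[j]);
    out[i] = tg[j] + fr * (tg[j + 1] - tg[j]);
  }
  for (int i = 1; i < np; ++i) if (out[i] < out[i - 1]) out[i] = out[i - 1];
}

static double chisq_cell(const std::vector<double>& rts_sorted, double n_cond,
                         double p_resp, double ter,
                         const std::vector<double>& qdec,
                         const std::vector<double>& mass, int min_count) {
  const double n_obs = (double)rts_sorted.size();
  const double e_prop = std::max(n_cond * p_resp, 1e-10);
  double stat = (n_obs - e_prop) * (n_obs - e_prop) / e_prop;
  if ((int)rts_sorted.size() < min_count) return stat;
  const int nb = (int)mass.size();        // = nq + 1 bins
  int lo = 0;
  for (int b = 0; b < nb; ++b) {
    int hi;
    if (b < nb - 1) {
      const double edge = ter + qdec[b];
      hi = (int)(std::lower_bound(rts_sorted.begin(), rts_sorted.end(), edge)
                 - rts_sorted.begin());
    } else {
      hi = (int)rts_sorted.size();
    }
    const double obs = (double)(hi - lo);
    const double exp_b = std::max(n_cond * p_resp * mass[b], 1e-10);
    stat += (obs - exp_b) * (obs - exp_b) / exp_b;
    lo = hi;
  }
  return stat;
}

// [[Rcpp::export]]
NumericVector cpp_qp_obj(NumericMatrix par, List def_rts, List coop_rts,
                         NumericVector probs, double s, int min_count) {
  const int pop = par.nrow();
  const int ncond = def_rts.size();
  const int np = probs.size();
  std::vector<double> pv(probs.begin(), probs.end());
  std::vector<double> mass(np + 1);
  mass[0] = pv[0];
  for (int i = 1; i < np; ++i) mass[i] = pv[i] - pv[i - 1];
  mass[np] = 1.0 - pv[np - 1];

  // copy observed data once
  std::vector< std::vector<double> > drt(ncond), crt(ncond);
  std::vector<double> ncond_tot(ncond);
  for (int c = 0; c < ncond; ++c) {
    NumericVector d = def_rts[c], cc = coop_rts[c];
    drt[c].assign(d.begin(), d.end());
    crt[c].assign(cc.begin(), cc.end());
    ncond_tot[c] = (double)(drt[c].size() + crt[c].size());
  }

  NumericVector out(pop);
  std::vector<double> qd, qc;
  for (int i = 0; i < pop; ++i) {
    const double ter = par(i, 3 * ncond);
    double stat = 0.0;
    bool bad = false;
    for (int c = 0; c < ncond && !bad; ++c) {
      const double v = par(i, 3 * c), a = par(i, 3 * c + 1), zz = par(i, 3 * c + 2);
      if (!(a > 0.0) || !(zz > 0.0) || !(zz < 1.0) || !std::isfinite(v)) {
        bad = true; break;
      }
      const double p_def = p_upper_impl(v, a, zz, s);
      grid_quantiles(v, a, zz, s, true,  p_def,       pv, qd);
      grid_quantiles(v, a, zz, s, false, 1.0 - p_def, pv, qc);
      stat += chisq_cell(drt[c], ncond_tot[c], p_def,       ter, qd, mass, min_count);
      stat += chisq_cell(crt[c], ncond_tot[c], 1.0 - p_def, ter, qc, mass, min_count);
    }
    out[i] = bad ? R_PosInf : stat;
  }
  return out;
}
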
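#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Fast seedable RNG for the inner simulation loop: xoshiro256++ uniforms
// with a Marsaglia-Tsang ziggurat for standard normals. The simulator runs
// millions of normal draws per objective evaluation, so this path matters.

static double zig_wn[128], zig_fn[128];
static uint32_t zig_kn[128];
static bool zig_ready = false;

static void zig_init() {
  const double m1 = 2147483648.0;  // 2^31: |hz| range of a signed 32-bit draw
  double dn = 3.442619855899, tn = dn;
  const double vn = 9.91256303526217e-3;
  double q = vn / std::exp(-0.5 * dn * dn);
  zig_kn[0] = (uint32_t)((dn / q) * m1);
  zig_kn[1] = 0;
  zig_wn[0] = q / m1;
  zig_wn[127] = dn / m1;
  zig_fn[0] = 1.0;
  zig_fn[127] = std::exp(-0.5 * dn * dn);
  for (int i = 126; i >= 1; --i) {
    dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
    zig_kn[i + 1] = (uint32_t)((dn / tn) * m1);
    tn = dn;
    zig_fn[i] = std::exp(-0.5 * dn * dn);
    zig_wn[i] = dn / m1;
  }
  zig_ready = true;
}

struct FastRng {
  uint64_t s[4];
  explicit FastRng(uint64_t seed) {
    if (!zig_ready) zig_init();
    // splitmix64 seeding
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next64() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    for (;;) {
      int32_t hz = (int32_t)(uint32_t)(next64() >> 32);
      uint32_t iz = (uint32_t)hz & 127u;
      uint32_t a = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (a < zig_kn[iz]) return hz * zig_wn[iz];
      if (iz == 0) {  // tail
        const double r = 3.442619855899;
        double x, y;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      double x = hz * zig_wn[iz];
      if (zig_fn[iz] + unif() * (zig_fn[iz - 1] - zig_fn[iz]) <
          std::exp(-0.5 * x * x)) {
        return x;
      }
      // rejected: resample from the top
    }
  }
};

// Parameter vector layout used throughout the compiled core:
// [0] sd_a0, [1] r_d, [2] p_input, [3] boundary, [4] ndt_mean, [5] ndt_sd

static inline double width_at(double t, double sd_a0, double r_d,
                              double width_floor) {
  double w = sd_a0 - r_d * t;
  return w > width_floor ? w : width_floor;
}

// target activation = Phi(0.5/sd) - Phi(-0.5/sd) = 2*Phi(0.5/sd) - 1
static inline double target_activation(double sd) {
  return 2.0 * R::pnorm(0.5 / sd, 0.0, 1.0, 1, 0) - 1.0;
}

// Per-step mean increments of the accumulator: drift rate (per ms) * dt.
// Congruent drift is p_input regardless of width (activations sum to 1);
// incongruent drift is p_input * (2*a_target - 1). Step k uses the width at
// the start of the step, t = k*dt.
static std::vector<double> drift_increments(double sd_a0, double r_d,
                                            double p_input, bool congruent,
                                            int n_steps, double dt,
                                            double width_floor) {
  std::vector<double> v(n_steps);
  for (int k = 0; k < n_steps; ++k) {
    if (congruent) {
      v[k] = p_input * dt;
    } else {
      double sd = width_at(k * dt, sd_a0, r_d, width_floor);
      v[k] = p_input * (2.0 * target_activation(sd) - 1.0) * dt;
    }
  }
  return v;
}

// [[Rcpp::export]]
NumericVector drift_schedule_cpp(double sd_a0, double r_d, double p_input,
                                 bool congruent, int n_steps, double dt,
                                 double width_floor) {
  std::vector<double> v = drift_increments(sd_a0, r_d, p_input, congruent,
                                           n_steps, dt, width_floor);
  NumericVector out(n_steps);
  for (int k = 0; k < n_steps; ++k) out[k] = v[k] / dt;  // rate per ms
  return out;
}

struct TrialBatch {
  std::vector<double> rt;      // NA-coded as -1 for censored
  std::vector<int> accuracy;   // -1 for censored
  std::vector<int> responded;
};

static void simulate_batch(const double* par, bool congruent, int n_trials,
                           double sigma, double dt, double width_floor,
                           double max_decision_time, FastRng& rng,
                           TrialBatch& out) {
  const double sd_a0 = par[0], r_d = par[1], p_input = par[2];
  const double b = par[3], ndt_mean = par[4], ndt_sd = par[5];
  const int n_steps = (int)std::ceil(max_decision_time / dt);
  const double step_sd = sigma * std::sqrt(dt);
  std::vector<double> v = drift_increments(sd_a0, r_d, p_input, congruent,
                                           n_steps, dt, width_floor);
  for (int i = 0; i < n_trials; ++i) {
    double x = 0.0;
    int crossed = 0, acc = -1;
    double decision_time = -1.0;
    for (int k = 0; k < n_steps; ++k) {
      x += v[k] + step_sd * rng.norm();
      if (x >= b || x <= -b) {
        crossed = 1;
        acc = (x >= b) ? 1 : 0;
        decision_time = (k + 1) * dt;
        break;
      }
    }
    if (crossed) {
      double ndt;
      if (ndt_sd <= 0.0) {
        ndt = ndt_mean > 0.0 ? ndt_mean : 0.0;
      } else {
        // normal truncated at zero, by rejection
        do {
          ndt = ndt_mean + ndt_sd * rng.norm();
        } while (ndt < 0.0);
      }
      out.rt.push_back(decision_time + ndt);
      out.accuracy.push_back(acc);
      out.responded.push_back(1);
    } else {
      out.rt.push_back(-1.0);
      out.accuracy.push_back(-1);
      out.responded.push_back(0);
    }
  }
}

// [[Rcpp::export]]
List simulate_trials_cpp(NumericVector params, int n_congruent,
                         int n_incongruent, double sigma, double dt,
                         double width_floor, double max_decision_time,
                         double seed) {
  FastRng rng((uint64_t)seed);
  TrialBatch batch;
  batch.rt.reserve(n_congruent + n_incongruent);
  simulate_batch(REAL(params), true, n_congruent, sigma, dt, width_floor,
                 max_decision_time, rng, batch);
  simulate_batch(REAL(params), false, n_incongruent, sigma, dt, width_floor,
                 max_decision_time, rng, batch);
  int n = (int)batch.rt.size();
  NumericVector rt(n);
  IntegerVector acc(n), resp(n);
  LogicalVector congruent(n);
  for (int i = 0; i < n; ++i) {
    resp[i] = batch.responded[i];
    congruent[i] = i < n_congruent;
    if (batch.responded[i]) {
      rt[i] = batch.rt[i];
      acc[i] = batch.accuracy[i];
    } else {
      rt[i] = NA_REAL;
      acc[i] = NA_INTEGER;
    }
  }
  return List::create(_["congruent"] = congruent, _["rt"] = rt,
                      _["accuracy"] = acc, _["responded"] = resp);
}

static inline int find_bin(double x, const double* edges, int n_edges) {
  // n_edges edges define n_edges + 1 bins; bin j is (edges[j-1], edges[j]]
  for (int j = 0; j < n_edges; ++j)
    if (x <= edges[j]) return j;
  return n_edges;
}

// Summed -2 log binomial deviance of one trial type's observed cells against
// proportions predicted by simulating `n_sim` trials at `params`.
// obs fields: n_total, cdf_edges (5), cdf_counts (6), caf_edges (3),
// caf_n (4), caf_k (4).
static double type_deviance(const double* par, bool congruent, int n_sim,
                            List obs, double sigma, double dt,
                            double width_floor, double max_decision_time,
                            FastRng& rng, double floor_mult) {
  NumericVector cdf_edges = obs["cdf_edges"];
  IntegerVector cdf_counts = obs["cdf_counts"];
  NumericVector caf_edges = obs["caf_edges"];
  IntegerVector caf_n = obs["caf_n"];
  IntegerVector caf_k = obs["caf_k"];
  int n_total = as<int>(obs["n_total"]);

  const int n_cdf = cdf_counts.size();   // 6
  const int n_caf = caf_n.size();        // 4
  std::vector<int> sim_cdf(n_cdf, 0), sim_caf_n(n_caf, 0), sim_caf_k(n_caf, 0);

  const double sd_a0 = par[0], r_d = par[1], p_input = par[2];
  const double b = par[3], ndt_mean = par[4], ndt_sd = par[5];
  const int n_steps = (int)std::ceil(max_decision_time / dt);
  const double step_sd = sigma * std::sqrt(dt);
  std::vector<double> v = drift_increments(sd_a0, r_d, p_input, congruent,
                                           n_steps, dt, width_floor);

  int n_responded = 0;
  for (int i = 0; i < n_sim; ++i) {
    double x = 0.0;
    int acc = -1;
    double decision_time = -1.0;
    for (int k = 0; k < n_steps; ++k) {
      x += v[k] + step_sd * rng.norm();
      if (x >= b || x <= -b) {
        acc = (x >= b) ? 1 : 0;
        decision_time = (k + 1) * dt;
        break;
      }
    }
    if (decision_time < 0.0) continue;  // censored
    double ndt;
    if (ndt_sd <= 0.0) {
      ndt = ndt_mean > 0.0 ? ndt_mean : 0.0;
    } else {
      do {
        ndt = ndt_mean + ndt_sd * rng.norm();
      } while (ndt < 0.0);
    }
    double rt = decision_time + ndt;
    ++n_responded;
    if (acc == 1) ++sim_cdf[find_bin(rt, REAL(cdf_edges), cdf_edges.size())];
    int cb = find_bin(rt, REAL(caf_edges), caf_edges.size());
    ++sim_caf_n[cb];
    if (acc == 1) ++sim_caf_k[cb];
  }

  if (n_responded == 0) return 1e12;  // no usable predictions at all
  const double p_floor = 1.0 / (floor_mult * n_responded);

  double dev = 0.0;
  for (int j = 0; j < n_cdf; ++j) {
    double pi = (double)sim_cdf[j] / n_responded;
    if (pi < p_floor) pi = p_floor;
    if (pi > 1.0 - p_floor) pi = 1.0 - p_floor;
    dev += -2.0 * R::dbinom(cdf_counts[j], n_total, pi, 1);
  }
  for (int j = 0; j < n_caf; ++j) {
    double pi;
    if (sim_caf_n[j] == 0) {
      pi = 0.5;  // bin unvisited by the model: uninformative accuracy
    } else {
      pi = (double)sim_caf_k[j] / sim_caf_n[j];
      if (pi < p_floor) pi = p_floor;
      if (pi > 1.0 - p_floor) pi = 1.0 - p_floor;
    }
    dev += -2.0 * R::dbinom(caf_k[j], caf_n[j], pi, 1);
  }
  return dev;
}

// [[Rcpp::export]]
double fit_objective_cpp(NumericVector params, List obs_congruent,
                         List obs_incongruent, int n_sim_congruent,
                         int n_sim_incongruent, double sigma, double dt,
                         double width_floor, double max_decision_time,
                         double seed, double floor_mult) {
  FastRng rng((uint64_t)seed);
  double dev = 0.0;
  dev += type_deviance(REAL(params), true, n_sim_congruent, obs_congruent,
                       sigma, dt, width_floor, max_decision_time, rng,
                       floor_mult);
  dev += type_deviance(REAL(params), false, n_sim_incongruent, obs_incongruent,
                       sigma, dt, width_floor, max_decision_time, rng,
                       floor_mult);
  return dev;
}
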
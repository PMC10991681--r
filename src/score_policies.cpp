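// Batch policy scorer: rolls planning particles forward under each candidate
// action sequence and accumulates per-step pragmatic and epistemic values.
// This duplicates the plain-R reference path (rollout(), pragmatic_value(),
// kde_entropy(), epistemic_value()) for speed inside the CEM loop; the test
// suite asserts the two paths agree on deterministic cases.
//
// State layouts (columns of the particle matrix):
//   scenario 1 (occlusion):   x vx ax y vy ay I ped_x ped_y C
//   scenario 2 (timesharing): x y theta delta v a w gaze Cl Cr
// Observations share the layout; null code -1000 marks unobservable values.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double NULL_CODE = -1000.0;
// squared scaled pair-distance saturation: see KDE_SQDIST_SAT in R/efe.R
static const double SQDIST_SAT = 60.0;
static const double LOG_2PI = 1.837877066409345483560659472811;

static inline double gauss_lp(double x, double mu, double sigma) {
  double z = (x - mu) / sigma;
  return -0.5 * LOG_2PI - std::log(sigma) - 0.5 * z * z;
}

// symmetric triangular on [-hw, hw] centred at 0; the floor is strongly
// unpreferred but not absolute (the absolute guard is the categorical
// lane-exit/conflict prior), matching TRI_FLOOR in R/priors.R
static const double TRI_FLOOR = -50.0;
static inline double tri_lp(double y, double hw) {
  double dens = (1.0 - std::fabs(y) / hw) / hw;
  if (dens <= 0.0) return TRI_FLOOR;
  return std::log(dens);
}

// Leave-one-out KDE entropy over d columns of (n x d) buffer `x` (row-major
// per particle), Scott's-rule bandwidth clipped to [h0, hcap], clamped at
// -10 per dim, minus the ambiguity constant d * log(sqrt(2*pi) * h0).
static double epistemic_kde(const std::vector<double>& x, int n, int d,
                            double h0, double hcap) {
  std::vector<double> h(d);
  double scott = std::pow((double)n, -1.0 / (d + 4.0));
  bool below_floor = true;
  for (int j = 0; j < d; ++j) {
    double m = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i) m += x[i * d + j];
    m /= n;
    for (int i = 0; i < n; ++i) {
      double dv = x[i * d + j] - m;
      ss += dv * dv;
    }
    double sd = std::sqrt(ss / (n - 1)); // sample sd, matches R's sd()
    if (sd > h0) below_floor = false;
    h[j] = std::min(std::max(sd * scott, h0), hcap);
  }
  // dispersion below the observation-resolution floor carries no epistemic
  // value; returning exactly 0 avoids estimator noise on degenerate beliefs
  if (below_floor) return 0.0;
  double log_norm = -0.5 * d * LOG_2PI;
  for (int j = 0; j < d; ++j) log_norm -= std::log(h[j]);
  double ent = 0.0;
  std::vector<double> lk(n);
  for (int i = 0; i < n; ++i) {
    double mx = -INFINITY;
    for (int jj = 0; jj < n; ++jj) {
      if (jj == i) { lk[jj] = -INFINITY; continue; }
      double sq = 0.0;
      for (int j = 0; j < d; ++j) {
        double dv = (x[i * d + j] - x[jj * d + j]) / h[j];
        sq += dv * dv;
      }
      if (sq > SQDIST_SAT) sq = SQDIST_SAT;
      lk[jj] = -0.5 * sq + log_norm;
      if (lk[jj] > mx) mx = lk[jj];
    }
    double s = 0.0;
    for (int jj = 0; jj < n; ++jj)
      if (std::isfinite(lk[jj])) s += std::exp(lk[jj] - mx);
    ent -= mx + std::log(s) - std::log((double)(n - 1));
  }
  ent /= n;
  if (ent < -10.0 * d) ent = -10.0 * d;
  return ent - d * std::log(std::sqrt(2.0 * M_PI) * h0);
}

// [[Rcpp::export]]
List score_policies_cpp(NumericMatrix particles, NumericVector cont,
                        Nullable<NumericVector> disc, int scenario,
                        List cfg,
                        Nullable<NumericVector> noise = R_NilValue) {
  IntegerVector cdim = cont.attr("dim"); // M x H x nc
  const int M = cdim[0], H = cdim[1], nc = cdim[2];
  const int N = particles.nrow(), S = particles.ncol();
  NumericVector dv;
  int nd = 0;
  if (disc.isNotNull()) {
    dv = disc.get();
    IntegerVector dd = dv.attr("dim");
    nd = dd[2];
  }

  const double dt = cfg["dt"];
  const double h0 = cfg["bandwidth_floor"];
  const double hcap = cfg["bandwidth_cap"];
  const double log_floor = cfg["log_floor"];
  const double speed_mu = cfg["speed_mu"], speed_sigma = cfg["speed_sigma"];
  const double accel_sigma = cfg["accel_sigma"];
  const double lane_hw = cfg["lane_half_width"];

  // scenario-specific parameters
  double cx = 0, cy = 0, px = 0, py = 0, safe = 0;
  bool lateral = false;
  double wheelbase = 0, sigma_w = 0, delta_max = 0, steer_sigma = 0,
         log_p_on = 0, log_p_off = 0;
  if (scenario == 1) {
    cx = cfg["corner_x"]; cy = cfg["corner_y"];
    px = cfg["ped_x"]; py = cfg["ped_y"];
    safe = cfg["safe_distance"];
    lateral = as<bool>(cfg["lateral_enabled"]);
  } else {
    wheelbase = cfg["wheelbase"]; sigma_w = cfg["sigma_w"];
    delta_max = cfg["delta_max"]; steer_sigma = cfg["steer_sigma"];
    log_p_on = cfg["log_p_on"];
    log_p_off = (log_p_on == 0.0) ? log_floor : std::log1p(-std::exp(log_p_on));
  }

  const int d_epi = 3;
  NumericVector G(M);
  NumericMatrix prag(M, H), epi(M, H);
  std::vector<double> st(N * S), epibuf(N * d_epi);

  // common random numbers: every policy (and, when `noise` is supplied by
  // the planner, every CEM iteration within a planning step) is rolled out
  // under the same process-noise realizations, so score differences reflect
  // actions rather than the noise lottery
  std::vector<double> eta;
  if (scenario == 2 && sigma_w > 0.0) {
    eta.resize(N * H);
    if (noise.isNotNull()) {
      NumericVector nv = noise.get();
      for (size_t i = 0; i < eta.size(); ++i) eta[i] = nv[i] * sigma_w;
    } else {
      for (size_t i = 0; i < eta.size(); ++i) eta[i] = R::norm_rand() * sigma_w;
    }
  }

  for (int m = 0; m < M; ++m) {
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < S; ++j) st[i * S + j] = particles(i, j);
    double g = 0.0;
    for (int t = 0; t < H; ++t) {
      double psum = 0.0;
      if (scenario == 1) {
        const double ax = cont[m + M * t];
        const double ay = (nc > 1) ? cont[m + M * (t + H)] : 0.0;
        for (int i = 0; i < N; ++i) {
          double* s = &st[i * S];
          // point mass: position with old velocity, then velocity update
          s[0] += s[1] * dt;
          s[3] += s[4] * dt;
          s[1] = std::max(0.0, s[1] + ax * dt);
          s[4] += ay * dt;
          s[2] = ax; s[5] = ay;
          bool present = s[6] > 0.5;
          // absorbing: a conflict stays on the predicted trajectory
          bool conflict = s[9] > 0.5 ||
                          (present && std::fabs(s[0] - s[7]) < safe) ||
                          (std::fabs(s[3]) > lane_hw);
          s[9] = conflict ? 1.0 : 0.0;
          // observation: visibility of the pedestrian site from the ego point
          double cross = (cx - s[0]) * (py - s[3]) - (cy - s[3]) * (px - s[0]);
          bool vis = cross >= 0.0;
          double o_I = vis ? 2.0 : 1.0;
          double o_px = vis ? s[7] : NULL_CODE;
          double o_py = vis ? s[8] : NULL_CODE;
          epibuf[i * 3 + 0] = o_I;
          epibuf[i * 3 + 1] = o_px;
          epibuf[i * 3 + 2] = o_py;
          // pragmatic: speed, accel (x and y), lane keeping if lateral,
          // absolute no-conflict prior
          double lp = gauss_lp(s[1], speed_mu, speed_sigma) +
                      gauss_lp(s[2], 0.0, accel_sigma) +
                      gauss_lp(s[5], 0.0, accel_sigma);
          if (lateral) lp += tri_lp(s[3], lane_hw);
          if (conflict) lp += log_floor;
          psum += lp;
        }
      } else {
        const double aa = cont[m + M * t];
        const double ww = cont[m + M * (t + H)];
        const int gz = (nd > 0) ? (dv[m + M * t] > 0.5 ? 1 : 0) : 1;
        for (int i = 0; i < N; ++i) {
          double* s = &st[i * S];
          double et = (sigma_w > 0.0) ? eta[i + N * t] : 0.0;
          s[3] += (ww + et) * dt;
          if (s[3] > delta_max) s[3] = delta_max;
          if (s[3] < -delta_max) s[3] = -delta_max;
          s[2] += s[4] / wheelbase * std::tan(s[3]) * dt;
          s[0] += s[4] * std::cos(s[2]) * dt;
          s[1] += s[4] * std::sin(s[2]) * dt;
          s[4] = std::max(0.0, s[4] + aa * dt);
          s[5] = aa; s[6] = ww; s[7] = gz;
          s[8] = (s[1] > lane_hw) ? 1.0 : 0.0;
          s[9] = (s[1] < -lane_hw) ? 1.0 : 0.0;
          // observation: x, y, theta nulled during off-road glances
          epibuf[i * 3 + 0] = gz ? s[0] : NULL_CODE;
          epibuf[i * 3 + 1] = gz ? s[1] : NULL_CODE;
          epibuf[i * 3 + 2] = gz ? s[2] : NULL_CODE;
          double lp = gauss_lp(s[4], speed_mu, speed_sigma) +
                      gauss_lp(s[5], 0.0, accel_sigma) +
                      gauss_lp(s[6], 0.0, steer_sigma) +
                      (gz ? log_p_on : log_p_off);
          if (gz) lp += tri_lp(s[1], lane_hw);
          if (s[8] > 0.5) lp += log_floor;
          if (s[9] > 0.5) lp += log_floor;
          psum += lp;
        }
      }
      double pv = psum / N;
      double ev = epistemic_kde(epibuf, N, d_epi, h0, hcap);
      prag(m, t) = pv;
      epi(m, t) = ev;
      g -= pv + ev;
    }
    G[m] = g;
  }
  return List::create(_["G"] = G, _["pragmatic"] = prag,
                      _["epistemic"] = epi);
}
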
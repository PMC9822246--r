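#include <Rcpp.h>
using namespace Rcpp;

// Wrap an angle to (-pi, pi].  floor-based to stay on widely available
// libm symbols.
static inline double wrap_angle(double a) {
  double t = (a + M_PI) / (2.0 * M_PI);
  a = (t - std::floor(t)) * 2.0 * M_PI;
  if (a <= 0.0) a += 2.0 * M_PI;
  return a - M_PI;
}

// One von Mises draw by the Best-Fisher (1979) rejection algorithm.
// kappa == 0 degenerates to the circular uniform on (-pi, pi].
static double rvm_one(double mu, double kappa) {
  if (kappa < 1e-10) return wrap_angle(unif_rand() * 2.0 * M_PI - M_PI);
  double a = 1.0 + std::sqrt(1.0 + 4.0 * kappa * kappa);
  double b = (a - std::sqrt(2.0 * a)) / (2.0 * kappa);
  double r = (1.0 + b * b) / (2.0 * b);
  double f = 0.0;
  for (;;) {
    double u1 = unif_rand();
    double z = std::cos(M_PI * u1);
    f = (1.0 + r * z) / (r + z);
    double c = kappa * (r - f);
    double u2 = unif_rand();
    if (c * (2.0 - c) - u2 > 0.0) break;
    if (std::log(c / u2) + 1.0 - c >= 0.0) break;
  }
  double u3 = unif_rand();
  double theta = (u3 > 0.5 ? 1.0 : -1.0) * std::acos(f);
  return wrap_angle(theta + mu);
}

// Normal(mean, sd) truncated to (0, Inf) by resampling.
static double rtnorm_pos_one(double mean, double sd) {
  if (sd <= 0.0) return mean;
  double v;
  do {
    v = mean + sd * norm_rand();
  } while (v <= 0.0);
  return v;
}

// [[Rcpp::export]]
NumericVector rvonmises_cpp(int n, double mu, double kappa) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rvm_one(mu, kappa);
  return out;
}

// [[Rcpp::export]]
NumericVector rtruncnorm_pos_cpp(int n, double mean, double sd) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rtnorm_pos_one(mean, sd);
  return out;
}

// Motor-state draws: 0 = crawl, 1 = turn, 2 = pause.  p_turn and p_pause are
// per-step probabilities (already scaled by dt).
// [[Rcpp::export]]
IntegerVector step_state_cpp(int n, double p_turn, double p_pause) {
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double u = unif_rand();
    if (u < p_turn) out[i] = 1;
    else if (u < p_turn + p_pause) out[i] = 2;
    else out[i] = 0;
  }
  return out;
}

// Index (0-based) of the substrate parameter set at (x, y): the first patch
// whose closed disc contains the point wins, otherwise the outside set.
static int param_idx_at(double x, double y,
                        const NumericMatrix &centers,
                        const NumericVector &radii,
                        const IntegerVector &patch_idx,
                        int outside_idx) {
  int np = centers.nrow();
  for (int p = 0; p < np; ++p) {
    double dx = x - centers(p, 0), dy = y - centers(p, 1);
    if (dx * dx + dy * dy <= radii[p] * radii[p]) return patch_idx[p];
  }
  return outside_idx;
}

// Piecewise-constant lookup of the inward-turn bias over half-open distance
// bins [edges[i], edges[i+1]); 0 outside the binned range.
static double bias_at(double d, const NumericVector &edges, const NumericVector &p) {
  int nb = p.size();
  for (int i = 0; i < nb; ++i) {
    if (d >= edges[i] && d < edges[i + 1]) return p[i];
  }
  return 0.0;
}

// Core agent loop of the crawl/turn/pause model.
//
// params: one row per parameter set, columns (mean_v, sd_v, p_turn_per_s,
// p_pause_per_s).  patch_param_idx maps each patch to a row; outside_param_idx
// is the row used outside every patch.  Bias, when enabled, redirects the turn
// toward the nearest patch center with probability Pbias(d) for distances
// below the cutoff (bins with Pbias = 0 leave the draw unbiased).
//
// All randomness comes from R's RNG stream, so set.seed() upstream makes the
// run fully reproducible.
// [[Rcpp::export]]
List simulate_cpp(int n_steps, double dt,
                  double arena_w, double arena_h,
                  NumericMatrix patch_centers, NumericVector patch_radii,
                  IntegerVector patch_param_idx, int outside_param_idx,
                  NumericMatrix params,
                  double mu, double kappa,
                  bool use_bias, NumericVector bias_edges, NumericVector bias_p,
                  double bias_cutoff,
                  double x0, double y0, double heading0) {
  NumericMatrix pos(n_steps + 1, 2);
  IntegerVector states(n_steps);
  std::vector<int> turn_step, turn_biased, turn_inward;
  std::vector<double> turn_x, turn_y, turn_angle, turn_dist;

  double x = x0, y = y0, h = heading0;
  pos(0, 0) = x; pos(0, 1) = y;
  int np = patch_centers.nrow();

  for (int k = 0; k < n_steps; ++k) {
    int pi = param_idx_at(x, y, patch_centers, patch_radii, patch_param_idx,
                          outside_param_idx);
    double p_turn = params(pi, 2) * dt;
    double p_pause = params(pi, 3) * dt;
    double u = unif_rand();
    if (u < p_turn) {
      // --- turn: rotate heading, no translation -------------------------
      states[k] = 1;
      double theta = rvm_one(mu, kappa);
      double d_near = NA_REAL;
      double h_new = h + theta;
      int biased = 0, inward_chosen = NA_INTEGER;
      if (np > 0) {
        // nearest patch center (lowest index on ties)
        int best = 0; double best_d2 = R_PosInf;
        for (int p = 0; p < np; ++p) {
          double dx = patch_centers(p, 0) - x, dy = patch_centers(p, 1) - y;
          double d2 = dx * dx + dy * dy;
          if (d2 < best_d2) { best_d2 = d2; best = p; }
        }
        d_near = std::sqrt(best_d2);
        if (use_bias && d_near <= bias_cutoff && d_near > 1e-12) {
          double pb = bias_at(d_near, bias_edges, bias_p);
          if (pb > 0.0) {
            double mag = std::fabs(theta);
            double ux = patch_centers(best, 0) - x;
            double uy = patch_centers(best, 1) - y;
            double ca = h + mag, cb = h - mag;  // the two turn options
            double da = std::acos(std::max(-1.0, std::min(1.0,
                          (std::cos(ca) * ux + std::sin(ca) * uy) / d_near)));
            double db = std::acos(std::max(-1.0, std::min(1.0,
                          (std::cos(cb) * ux + std::sin(cb) * uy) / d_near)));
            double inward = (da <= db) ? ca : cb;
            double outward = (da <= db) ? cb : ca;
            biased = 1;
            inward_chosen = (unif_rand() < pb) ? 1 : 0;
            h_new = inward_chosen ? inward : outward;
          }
        }
      }
      double realized = wrap_angle(h_new - h);
      h = wrap_angle(h_new);
      turn_step.push_back(k + 1);
      turn_x.push_back(x); turn_y.push_back(y);
      turn_angle.push_back(realized); turn_dist.push_back(d_near);
      turn_biased.push_back(biased); turn_inward.push_back(inward_chosen);
    } else if (u < p_turn + p_pause) {
      // --- pause: freeze ------------------------------------------------
      states[k] = 2;
    } else {
      // --- crawl --------------------------------------------------------
      states[k] = 0;
      double v = rtnorm_pos_one(params(pi, 0), params(pi, 1));
      double nx = x + std::cos(h) * v * dt;
      double ny = y + std::sin(h) * v * dt;
      if (nx < 0.0 || nx > arena_w || ny < 0.0 || ny > arena_h) {
        // rigid wall: truncate at the boundary, then point the heading
        // back into the arena (uniform over inward directions)
        nx = std::max(0.0, std::min(arena_w, nx));
        ny = std::max(0.0, std::min(arena_h, ny));
        for (int tries = 0; tries < 1000; ++tries) {
          double cand = unif_rand() * 2.0 * M_PI - M_PI;
          double cx = std::cos(cand), cy = std::sin(cand);
          bool ok = true;
          if (nx <= 0.0 && cx <= 0.0) ok = false;
          if (nx >= arena_w && cx >= 0.0) ok = false;
          if (ny <= 0.0 && cy <= 0.0) ok = false;
          if (ny >= arena_h && cy >= 0.0) ok = false;
          if (ok) { h = cand; break; }
        }
      }
      x = nx; y = ny;
    }
    pos(k + 1, 0) = x; pos(k + 1, 1) = y;
  }

  return List::create(
    _["positions"] = pos,
    _["states"] = states,
    _["turn_step"] = wrap(turn_step),
    _["turn_x"] = wrap(turn_x),
    _["turn_y"] = wrap(turn_y),
    _["turn_angle"] = wrap(turn_angle),
    _["turn_dist"] = wrap(turn_dist),
    _["turn_biased"] = wrap(turn_biased),
    _["turn_inward"] = wrap(turn_inward));
}
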
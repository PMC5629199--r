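#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time kinetic Monte Carlo on a row-stochastic matrix.
// Draws u ~ U[0,1) per step via R's RNG and applies the cumulative-sum
// rule: next state is the first j with running sum S_j > u.
// Returns the visited states (0-based), truncated at the first entry into
// `stop_states` when stop_states is non-empty.
// [[Rcpp::export]]
IntegerVector kmc_run_cpp(NumericMatrix tmat, int start, int nsteps,
                          IntegerVector stop_states) {
  int n = tmat.nrow();
  std::vector<bool> is_stop(n, false);
  for (int k = 0; k < stop_states.size(); ++k) is_stop[stop_states[k]] = true;
  std::vector<int> out;
  out.reserve(nsteps + 1);
  int state = start;
  out.push_back(state);
  RNGScope scope;
  for (int step = 0; step < nsteps; ++step) {
    double u = unif_rand();
    double s = 0.0;
    int nxt = -1;
    for (int j = 0; j < n; ++j) {
      s += tmat(state, j);
      if (u < s) { nxt = j; break; }
    }
    if (nxt < 0) nxt = n - 1;  // guard against rounding at u ~ 1
    state = nxt;
    out.push_back(state);
    if (is_stop[state]) break;
  }
  return wrap(out);
}

// Overdamped 2-D Brownian dynamics by Euler-Maruyama on a sum of Gaussian
// wells plus an optional harmonic confinement:
//   x_{t+1} = x_t - (D dt / kT) grad U(x_t) + sqrt(2 D dt) xi_t.
// wells: columns cx, cy, depth (>0, well depth), width. conf: cx, cy, kappa.
// target: tx, ty, radius (radius <= 0 disables hit detection). Frames are
// stored every `thin` steps (frame 0 always stored); the hit test runs at
// every step and, when stop_at_target, integration ends at the hit.
// [[Rcpp::export]]
List brownian_run_cpp(NumericMatrix wells, NumericVector conf,
                      double D, double dt, double kT, int nsteps,
                      NumericVector x0, NumericVector target,
                      bool stop_at_target, int thin, double guard) {
  int nw = wells.nrow();
  double x = x0[0], y = x0[1];
  double pref = D * dt / kT;
  double noise = std::sqrt(2.0 * D * dt);
  bool has_target = target[2] > 0.0;
  double tr2 = target[2] * target[2];
  std::vector<double> fx, fy;
  fx.reserve(nsteps / thin + 2);
  fy.reserve(nsteps / thin + 2);
  fx.push_back(x); fy.push_back(y);
  int hit_step = -1;
  if (has_target) {
    double dx = x - target[0], dy = y - target[1];
    if (dx * dx + dy * dy <= tr2) hit_step = 0;
  }
  RNGScope scope;
  int step = 0;
  if (hit_step < 0 || !stop_at_target) {
    for (step = 1; step <= nsteps; ++step) {
      double gx = conf[2] * (x - conf[0]);
      double gy = conf[2] * (y - conf[1]);
      for (int w = 0; w < nw; ++w) {
        double dx = x - wells(w, 0), dy = y - wells(w, 1);
        double w2 = wells(w, 3) * wells(w, 3);
        double e = wells(w, 2) * std::exp(-(dx * dx + dy * dy) / (2.0 * w2));
        gx += e * dx / w2;
        gy += e * dy / w2;
      }
      x += -pref * gx + noise * norm_rand();
      y += -pref * gy + noise * norm_rand();
      if (std::fabs(x) > guard || std::fabs(y) > guard)
        stop("Brownian integration diverged (|x| > guard); use a smaller dt");
      if (step % thin == 0) { fx.push_back(x); fy.push_back(y); }
      if (has_target && hit_step < 0) {
        double dx = x - target[0], dy = y - target[1];
        if (dx * dx + dy * dy <= tr2) {
          hit_step = step;
          if (stop_at_target) break;
        }
      }
    }
    if (step <= nsteps && (step % thin) != 0) {  // store final frame
      fx.push_back(x); fy.push_back(y);
    }
  }
  int nf = fx.size();
  NumericMatrix traj(nf, 2);
  for (int i = 0; i < nf; ++i) { traj(i, 0) = fx[i]; traj(i, 1) = fy[i]; }
  return List::create(_["traj"] = traj, _["hit_step"] = hit_step);
}
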
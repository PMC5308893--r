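#include <Rcpp.h>
using namespace Rcpp;

// Per-frame simulation of an open-field session.
//
// Dynamics (Euler step dt):
//   state   : discrete behavioral state, Markov chain with per-second rate
//             matrix `rates` (off-diagonal entries; diagonal ignored). While
//             stimulation is on, rates from mobile states (is_mobile) into
//             the resting state (rest_state) are multiplied by rest_boost.
//   v_base  : mean-reverting (OU) speed, dv = theta*(mu - v)dt + sigma*sqrt(dt)*N,
//             clamped at 0.
//   gain    : relaxes toward gain_target[i] with time constant tau_on while
//             stim_on[i], and toward 1 with tau_off otherwise.
//   heading : diffuses with sd sqrt(dt/kappa); with w_wall > 0 it is steered
//             toward the nearest wall point at angular rate w_wall (rad/s).
//   position: step = state_mult[state] * v_base * gain * dt along heading,
//             reflected at the walls (heading reflected too).
//
// In roi_mode the stimulation indicator is positional (centroid inside the
// half-open ROI rectangle) rather than the stim_on schedule.
//
// Uses R's RNG so results are reproducible under set.seed().

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(int n, double dt,
              double arena_w, double arena_h,
              double mu_v, double theta, double sigma_v,
              double kappa, double w_wall,
              NumericVector state_mult, NumericMatrix rates,
              LogicalVector is_mobile, int rest_state,
              double tau_on, double tau_off, double rest_boost,
              LogicalVector stim_on, NumericVector gain_target,
              bool roi_mode, double roi_x0, double roi_y0,
              double roi_w, double roi_h, double roi_gain,
              double x0, double y0, double heading0, double v0, int state0) {
  RNGScope scope;
  const int n_states = state_mult.size();
  NumericVector x(n), y(n), v_true(n), gain_out(n);
  IntegerVector state(n);
  LogicalVector stim_applied(n);

  double xx = x0, yy = y0, phi = heading0, vb = v0, g = 1.0;
  int st = state0;  // 0-based
  const double sd_head = std::sqrt(dt / kappa);
  const double sd_v = sigma_v * std::sqrt(dt);
  const double cx = arena_w / 2.0, cy = arena_h / 2.0;

  for (int i = 0; i < n; ++i) {
    bool on;
    double gt;
    if (roi_mode) {
      on = (xx >= roi_x0 && xx < roi_x0 + roi_w &&
            yy >= roi_y0 && yy < roi_y0 + roi_h);
      gt = roi_gain;
    } else {
      on = stim_on[i];
      gt = gain_target[i];
    }

    // state transition: switch prob rate*dt per destination
    double u = R::runif(0.0, 1.0), acc = 0.0;
    int nxt = st;
    for (int s = 0; s < n_states; ++s) {
      if (s == st) continue;
      double r = rates(st, s);
      if (on && is_mobile[st] && s == rest_state) r *= rest_boost;
      acc += r * dt;
      if (u < acc) { nxt = s; break; }
    }
    st = nxt;

    // OU speed
    vb += theta * (mu_v - vb) * dt + sd_v * norm_rand();
    if (vb < 0.0) vb = 0.0;

    // stimulation gain
    if (on) g += (gt - g) * dt / tau_on;
    else    g += (1.0 - g) * dt / tau_off;

    // heading: diffusion + steering toward nearest wall point
    phi += sd_head * norm_rand();
    if (w_wall > 0.0) {
      // nearest wall point: project along the shorter of dx/dy margins
      double dl = xx, dr = arena_w - xx, db = yy, dtp = arena_h - yy;
      double target;
      double m = std::min(std::min(dl, dr), std::min(db, dtp));
      if (m == dl) target = M_PI;            // toward left wall
      else if (m == dr) target = 0.0;        // right
      else if (m == db) target = -M_PI_2;    // bottom
      else target = M_PI_2;                  // top
      phi += w_wall * dt * std::sin(target - phi);
    }

    double sp = state_mult[st] * vb * g;
    xx += sp * std::cos(phi) * dt;
    yy += sp * std::sin(phi) * dt;

    // reflect at walls
    if (xx < 0.0)       { xx = -xx; phi = M_PI - phi; }
    if (xx > arena_w)   { xx = 2.0 * arena_w - xx; phi = M_PI - phi; }
    if (yy < 0.0)       { yy = -yy; phi = -phi; }
    if (yy > arena_h)   { yy = 2.0 * arena_h - yy; phi = -phi; }
    // pathological double-overshoot cannot happen for sp*dt << arena size,
    // but clamp defensively
    if (xx < 0.0) xx = 0.0;
    if (xx > arena_w) xx = arena_w;
    if (yy < 0.0) yy = 0.0;
    if (yy > arena_h) yy = arena_h;

    x[i] = xx; y[i] = yy; v_true[i] = sp;
    state[i] = st + 1;  // 1-based for R
    gain_out[i] = g;
    stim_applied[i] = on;
  }
  (void)cx; (void)cy;

  return List::create(_["x"] = x, _["y"] = y, _["state"] = state,
                      _["v_true"] = v_true, _["gain"] = gain_out,
                      _["stim_on"] = stim_applied);
}

// Running median with shrunken symmetric windows at the boundaries.
// NA centers stay NA; NAs within a window are dropped from the median.
// [[Rcpp::export(name = ".median_filter")]]
NumericVector median_filter_cpp(NumericVector v, int k) {
  const int n = v.size();
  const int h = (k - 1) / 2;
  NumericVector out(n, NA_REAL);
  std::vector<double> buf;
  buf.reserve(k);
  for (int i = 0; i < n; ++i) {
    if (NumericVector::is_na(v[i])) continue;
    int hi = std::min(h, std::min(i, n - 1 - i));
    buf.clear();
    for (int j = i - hi; j <= i + hi; ++j)
      if (!NumericVector::is_na(v[j])) buf.push_back(v[j]);
    if (buf.empty()) continue;
    std::sort(buf.begin(), buf.end());
    size_t m = buf.size();
    out[i] = (m % 2 == 1) ? buf[m / 2] : 0.5 * (buf[m / 2 - 1] + buf[m / 2]);
  }
  return out;
}
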
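#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fixed-step Euler predictor-corrector (Heun) integration of the coupled
// five-gene + repressor-signal system on a 1D no-flux lattice.
//
// State layout: 6 fields x n cells (lfy, ap1, ag, tfl1, wus, y).
// The AG time gate is evaluated by step index (gate_step = gate_time / dt) so
// that the opening time is exact in integer arithmetic; the predictor stage of
// the step starting at step s uses gate(s), the corrector stage gate(s + 1).
//
// The coupling coefficient epsilon is supplied as an epoch-by-cell matrix:
// epoch r is active for steps [r * eps_every, (r+1) * eps_every); the last row
// persists to the end. A single row gives a time-constant schedule.

namespace {

struct Fields {
  std::vector<double> lfy, ap1, ag, tfl1, wus, y;
  explicit Fields(int n) : lfy(n), ap1(n), ag(n), tfl1(n), wus(n), y(n) {}
};

// mirrored-ghost-cell second difference: ends see their own value reflected,
// so sums telescope to exactly zero (no-flux conservation)
inline double lap(const std::vector<double>& v, int j, int n) {
  const double left  = (j == 0)     ? v[0]     : v[j - 1];
  const double right = (j == n - 1) ? v[n - 1] : v[j + 1];
  return left + right - 2.0 * v[j];
}

inline double sigmoid(double u, int variant) {
  switch (variant) {
  case 0:  return 0.5 * (1.0 + u / std::sqrt(1.0 + u * u)); // mjolsness
  case 1:  return (1.0 + u) / (1.0 + u * u);                // literal_ratio
  default: return 1.0 + u / (1.0 + u * u);                  // literal_sum
  }
}

} // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericVector lfy0, NumericVector ap10, NumericVector ag0,
              NumericVector tfl10, NumericVector wus0, NumericVector y0,
              NumericVector L, NumericVector kin, NumericMatrix eps,
              int eps_every, NumericVector wp, int sigmoid_variant,
              int gate_step, int gate_scope, int denom_scope,
              int ap1_feedback, int excl_driver, bool clip_negative,
              bool euler_only, double dt, int n_steps, int sample_every) {
  const int n = lfy0.size();
  if (n < 3) stop("lattice needs at least 3 cells");
  // kin: k1..k16 (0..15), beta1 (16), beta2 (17), beta3 (18)
  const double k1 = kin[0], k2 = kin[1], k3 = kin[2], k4 = kin[3];
  const double k5 = kin[4], k6 = kin[5], k7 = kin[6], k8 = kin[7];
  const double k9 = kin[8], k10 = kin[9], k11 = kin[10], k12 = kin[11];
  const double k13 = kin[12], k14 = kin[13], k15 = kin[14], k16 = kin[15];
  const double beta1 = kin[16], beta2 = kin[17], beta3 = kin[18];
  // wp: k17_eff (0), d_w (1), h_w (2), T_wy (3), k_y (4), d_y (5), D_y (6),
  //     inv_time_scale (7)
  const double k17e = wp[0], d_w = wp[1], h_w = wp[2], T_wy = wp[3];
  const double k_y = wp[4], d_y = wp[5], D_y = wp[6], its = wp[7];

  Fields x(n), pred(n), d1(n), d2(n);
  for (int j = 0; j < n; ++j) {
    x.lfy[j] = lfy0[j]; x.ap1[j] = ap10[j]; x.ag[j] = ag0[j];
    x.tfl1[j] = tfl10[j]; x.wus[j] = wus0[j]; x.y[j] = y0[j];
  }

  const int n_epochs = eps.nrow();
  const int eps_cols = eps.ncol();

  const int n_samples = n_steps / sample_every +
                        ((n_steps % sample_every) ? 2 : 1);
  NumericVector times(n_samples);
  NumericMatrix s_lfy(n_samples, n), s_ap1(n_samples, n), s_ag(n_samples, n),
      s_tfl1(n_samples, n), s_wus(n_samples, n), s_y(n_samples, n);
  IntegerVector clip_counts(6); // per-field corrector clips

  auto rhs = [&](const Fields& s, int step, Fields& d) {
    const double gate = (step >= gate_step) ? 1.0 : 0.0;
    int epoch = (eps_every > 0) ? step / eps_every : 0;
    if (epoch >= n_epochs) epoch = n_epochs - 1;
    for (int j = 0; j < n; ++j) {
      const double lfy = s.lfy[j], ap1 = s.ap1[j], ag = s.ag[j];
      const double tfl1 = s.tfl1[j], wus = s.wus[j], y = s.y[j];
      const double excl = (excl_driver == 0) ? ag : wus;
      const double ap1T = ap1 * (1.0 - excl / (excl + beta1));
      const double ap1_in = (ap1_feedback == 0) ? ap1 : ap1T; // raw | effective
      const double e = eps[(eps_cols == 1) ? epoch
                                           : epoch + n_epochs * j];
      d.lfy[j] = k1 + k2 * ap1_in - k3 * tfl1 - k4 * lfy +
                 e * lap(s.lfy, j, n);
      d.ap1[j] = k5 + k6 * lfy - k7 * tfl1 - k8 * ap1;
      const double denom = beta2 + beta3 * ap1_in;
      double prod;
      if (denom_scope == 0) { // noncompetitive inhibition on total production
        prod = (gate_scope == 0) ? gate * (k9 * wus + k10 * lfy) / denom
                                 : (gate * k9 * wus + k10 * lfy) / denom;
      } else {               // inhibition on the LFY term only
        prod = (gate_scope == 0) ? gate * (k9 * wus + k10 * lfy / denom)
                                 : gate * k9 * wus + k10 * lfy / denom;
      }
      d.ag[j] = prod - k11 * tfl1 - k12 * ag;
      d.tfl1[j] = k13 - k14 * lfy - k15 * ap1_in - k16 * tfl1;
      const double u = h_w + T_wy * y;
      d.wus[j] = its * (k17e * sigmoid(u, sigmoid_variant) - d_w * wus);
      d.y[j] = its * (k_y * L[j] - d_y * y + D_y * lap(s.y, j, n));
    }
  };

  auto record = [&](int row, double t) {
    times[row] = t;
    for (int j = 0; j < n; ++j) {
      s_lfy(row, j) = x.lfy[j]; s_ap1(row, j) = x.ap1[j];
      s_ag(row, j) = x.ag[j]; s_tfl1(row, j) = x.tfl1[j];
      s_wus(row, j) = x.wus[j]; s_y(row, j) = x.y[j];
    }
  };

  int row = 0;
  record(row++, 0.0);

  std::vector<double>* fx[6] = {&x.lfy, &x.ap1, &x.ag, &x.tfl1, &x.wus, &x.y};
  std::vector<double>* fp[6] = {&pred.lfy, &pred.ap1, &pred.ag,
                                &pred.tfl1, &pred.wus, &pred.y};
  std::vector<double>* f1[6] = {&d1.lfy, &d1.ap1, &d1.ag,
                                &d1.tfl1, &d1.wus, &d1.y};
  std::vector<double>* f2[6] = {&d2.lfy, &d2.ap1, &d2.ag,
                                &d2.tfl1, &d2.wus, &d2.y};

  for (int s = 0; s < n_steps; ++s) {
    rhs(x, s, d1);
    if (euler_only) {
      for (int f = 0; f < 6; ++f)
        for (int j = 0; j < n; ++j) {
          double v = (*fx[f])[j] + dt * (*f1[f])[j];
          if (clip_negative && v < 0.0) { v = 0.0; ++clip_counts[f]; }
          (*fx[f])[j] = v;
        }
    } else {
      for (int f = 0; f < 6; ++f)
        for (int j = 0; j < n; ++j)
          (*fp[f])[j] = (*fx[f])[j] + dt * (*f1[f])[j];
      rhs(pred, s + 1, d2);
      for (int f = 0; f < 6; ++f)
        for (int j = 0; j < n; ++j) {
          double v = (*fx[f])[j] +
                     0.5 * dt * ((*f1[f])[j] + (*f2[f])[j]);
          if (clip_negative && v < 0.0) { v = 0.0; ++clip_counts[f]; }
          (*fx[f])[j] = v;
        }
    }
    if ((s + 1) % sample_every == 0 || s + 1 == n_steps) {
      for (int j = 0; j < n; ++j)
        if (!std::isfinite(x.lfy[j]) || !std::isfinite(x.ap1[j]) ||
            !std::isfinite(x.ag[j]) || !std::isfinite(x.tfl1[j]) ||
            !std::isfinite(x.wus[j]) || !std::isfinite(x.y[j]))
          stop("integration unstable: non-finite state at step %d", s + 1);
      record(row++, (s + 1) * dt);
    }
  }

  return List::create(
      _["times"] = times[Range(0, row - 1)],
      _["lfy"] = s_lfy(Range(0, row - 1), _),
      _["ap1"] = s_ap1(Range(0, row - 1), _),
      _["ag"] = s_ag(Range(0, row - 1), _),
      _["tfl1"] = s_tfl1(Range(0, row - 1), _),
      _["wus"] = s_wus(Range(0, row - 1), _),
      _["y"] = s_y(Range(0, row - 1), _),
      _["clip_counts"] = clip_counts);
}
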
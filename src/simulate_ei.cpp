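#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of the coupled E/I population equations.
//
// Each gamma-kernel convolution y = f * u (f the unit-area kernel with
// time-constant tau) is realized as the critically damped second-order
// filter tau^2 y'' + 2 tau y' + y = u, carried as the state pair (y, y').
// Four such filters are needed:
//   A = f_e * x_e                      (feeds the inhibitory equation)
//   B = f_i * x_i                      (feeds the excitatory equation)
//   C = f_e * (g_ee x_e - g_ei B)      (excitatory decay drive)
//   D = f_i * (g_ii x_i + g_ei A)      (inhibitory decay drive)
// and the population signals obey
//   dx_e/dt = -C / tau_e + p1(t)
//   dx_i/dt = -D / tau_i + p2(t)
//
// The scheme runs `substeps` Euler steps per output sample (dt_int =
// dt/substeps) because the forward-Euler stability disk requires
// dt < -2 Re(lambda)/|lambda|^2 for the lightly damped resonant poles.
// White noise is drawn from R's RNG (norm_rand), one draw per substep
// (two under independent drives), with sd noise_sd/sqrt(dt_int);
// the Euler increment is p * dt_int. Integration aborts once any state
// exceeds 1e12 in magnitude.
// [[Rcpp::export]]
List simulate_ei_cpp(double tau_e, double tau_i,
                     double g_ee, double g_ii, double g_ei,
                     double noise_sd, bool common_noise,
                     double dt, int n, int substeps,
                     NumericVector init) {
  NumericVector xe_out(n), xi_out(n);

  double xe = init.size() > 0 ? init[0] : 0.0;
  double xi = init.size() > 1 ? init[1] : 0.0;
  // filter states (value, derivative)
  double Ay = 0, Av = 0, By = 0, Bv = 0, Cy = 0, Cv = 0, Dy = 0, Dv = 0;
  const double te2 = tau_e * tau_e, ti2 = tau_i * tau_i;
  const double h = dt / substeps;
  const double psd = noise_sd / std::sqrt(h);
  bool stable = true;
  RNGScope scope;

  for (int k = 0; k < n && stable; ++k) {
    for (int j = 0; j < substeps; ++j) {
      const double p1 = noise_sd > 0 ? psd * norm_rand() : 0.0;
      const double p2 = common_noise ? p1
                        : (noise_sd > 0 ? psd * norm_rand() : 0.0);
      const double uA = xe;
      const double uB = xi;
      const double uC = g_ee * xe - g_ei * By;
      const double uD = g_ii * xi + g_ei * Ay;

      const double Av_new = Av + h * (uA - Ay - 2.0 * tau_e * Av) / te2;
      const double Ay_new = Ay + h * Av;
      const double Bv_new = Bv + h * (uB - By - 2.0 * tau_i * Bv) / ti2;
      const double By_new = By + h * Bv;
      const double Cv_new = Cv + h * (uC - Cy - 2.0 * tau_e * Cv) / te2;
      const double Cy_new = Cy + h * Cv;
      const double Dv_new = Dv + h * (uD - Dy - 2.0 * tau_i * Dv) / ti2;
      const double Dy_new = Dy + h * Dv;

      xe += h * (-Cy / tau_e) + h * p1;
      xi += h * (-Dy / tau_i) + h * p2;
      Ay = Ay_new; Av = Av_new; By = By_new; Bv = Bv_new;
      Cy = Cy_new; Cv = Cv_new; Dy = Dy_new; Dv = Dv_new;

      if (std::fabs(xe) > 1e12 || std::fabs(xi) > 1e12 ||
          std::fabs(Cy) > 1e12 || std::fabs(Dy) > 1e12) {
        stable = false;
        break;
      }
    }
    xe_out[k] = xe;
    xi_out[k] = xi;
  }
  return List::create(_["x_e"] = xe_out, _["x_i"] = xi_out,
                      _["stable"] = stable);
}
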
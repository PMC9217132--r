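#include <Rcpp.h>
#include <R_ext/Applic.h>
#include <complex>
using namespace Rcpp;

// Basin-hopping global optimization of the Pearson spectral cost, run
// entirely at C level: random coordinate displacement, bounded
// quasi-Newton (L-BFGS-B, R's own implementation) local minimization,
// and Metropolis acceptance on the cost scale. Proposals and acceptance
// draws use R's RNG, so results are reproducible under set.seed().

struct CostData {
  const double *w;
  const double *emp_c;
  double emp_ss;
  double g_ei;
  bool common;
  int n;
  long n_eval;
};

static double spectral_cost(int npar, double *theta, void *ex) {
  CostData *cd = static_cast<CostData *>(ex);
  ++cd->n_eval;
  const double te = theta[0] / 1000.0, ti = theta[1] / 1000.0;
  const double gee = theta[2], gii = theta[3];
  double mean = 0.0;
  // two passes: model dB, then centred correlation
  std::vector<double> db(cd->n);
  for (int k = 0; k < cd->n; ++k) {
    const std::complex<double> jw(0.0, cd->w[k]);
    const std::complex<double> Fe = 1.0 / ((1.0 + jw * te) * (1.0 + jw * te));
    const std::complex<double> Fi = 1.0 / ((1.0 + jw * ti) * (1.0 + jw * ti));
    const std::complex<double> ae = Fe / te, ai = Fi / ti;
    const std::complex<double> a = jw + ae * gee;
    const std::complex<double> b = -ae * cd->g_ei * Fi;
    const std::complex<double> c = ai * cd->g_ei * Fe;
    const std::complex<double> d = jw + ai * gii;
    const std::complex<double> det = a * d - b * c;
    double lin;
    if (cd->common) {
      lin = std::norm((d - b + a - c) / det);
    } else {
      lin = (std::norm(d - b) + std::norm(a - c)) / std::norm(det);
    }
    if (!(lin > 0.0) || !std::isfinite(lin)) return 2.0;
    db[k] = 10.0 * std::log10(lin);
    mean += db[k];
  }
  mean /= cd->n;
  double num = 0.0, ss = 0.0;
  for (int k = 0; k < cd->n; ++k) {
    const double cc = db[k] - mean;
    num += cd->emp_c[k] * cc;
    ss += cc * cc;
  }
  if (ss <= 0.0) return 2.0;
  return -num / (cd->emp_ss * std::sqrt(ss));
}

static void spectral_cost_grad(int npar, double *theta, double *grad,
                               void *ex) {
  double th[4];
  for (int j = 0; j < 4; ++j) th[j] = theta[j];
  for (int j = 0; j < 4; ++j) {
    const double h = 1e-6 * std::max(1.0, std::fabs(theta[j]));
    th[j] = theta[j] + h;
    const double up = spectral_cost(npar, th, ex);
    th[j] = theta[j] - h;
    const double lo = spectral_cost(npar, th, ex);
    th[j] = theta[j];
    grad[j] = (up - lo) / (2.0 * h);
  }
}

// one bounded L-BFGS-B local minimization from x (overwritten in place);
// returns the achieved cost
static double local_min(double *x, double *lower, double *upper,
                        int maxit, double factr, CostData *cd) {
  int nbd[4] = {2, 2, 2, 2};           // both bounds active
  double fmin = 0.0;
  int fail = 0, fncount = 0, grcount = 0;
  char msg[256];
  lbfgsb(4, 5, x, lower, upper, nbd, &fmin,
         spectral_cost, spectral_cost_grad, &fail,
         static_cast<void *>(cd), factr, 1e-10,
         &fncount, &grcount, maxit, msg, 0, 10);
  if (fail != 0 && !std::isfinite(fmin))
    fmin = spectral_cost(4, x, static_cast<void *>(cd));
  return fmin;
}

// [[Rcpp::export]]
List basin_hop_cpp(NumericVector w, NumericVector emp_c, double emp_ss,
                   double g_ei, bool common,
                   NumericVector init, NumericVector lower,
                   NumericVector upper, int n_iterations,
                   double temperature, double step_size,
                   int maxit_local, double factr) {
  CostData cd;
  cd.w = REAL(w);
  cd.emp_c = REAL(emp_c);
  cd.emp_ss = emp_ss;
  cd.g_ei = g_ei;
  cd.common = common;
  cd.n = w.size();
  cd.n_eval = 0;

  RNGScope scope;
  double lo[4], up[4], cur[4], best[4], prop[4];
  for (int j = 0; j < 4; ++j) {
    lo[j] = lower[j];
    up[j] = upper[j];
    cur[j] = init[j];
  }
  double cur_val = local_min(cur, lo, up, maxit_local, factr, &cd);
  double best_val = cur_val;
  for (int j = 0; j < 4; ++j) best[j] = cur[j];

  for (int i = 0; i < n_iterations; ++i) {
    for (int j = 0; j < 4; ++j) {
      prop[j] = cur[j] + unif_rand() * 2.0 * step_size - step_size;
      if (prop[j] < lo[j]) prop[j] = lo[j];
      if (prop[j] > up[j]) prop[j] = up[j];
    }
    const double val = local_min(prop, lo, up, maxit_local, factr, &cd);
    if (val < best_val) {
      best_val = val;
      for (int j = 0; j < 4; ++j) best[j] = prop[j];
    }
    const bool accept = val <= cur_val ||
      unif_rand() < std::exp(-(val - cur_val) / temperature);
    if (accept) {
      cur_val = val;
      for (int j = 0; j < 4; ++j) cur[j] = prop[j];
    }
  }
  return List::create(_["par"] = NumericVector(best, best + 4),
                      _["value"] = best_val,
                      _["n_eval"] = static_cast<double>(cd.n_eval));
}
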
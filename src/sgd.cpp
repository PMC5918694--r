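#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// mean logistic loss + elastic-net penalty on w (intercept b unpenalized).
// Xt is features x samples so each sample is a contiguous column.
static double objective(const NumericMatrix& Xt, const NumericVector& y,
                        const std::vector<double>& w, double b,
                        double lam1, double lam2) {
  const int p = Xt.nrow(), n = Xt.ncol();
  double loss = 0.0;
  for (int i = 0; i < n; ++i) {
    double m = b;
    const double* xi = &Xt(0, i);
    for (int j = 0; j < p; ++j) m += w[j] * xi[j];
    // log(1 + exp(m)) - y*m, computed stably
    double lse = (m > 0) ? m + std::log1p(std::exp(-m)) : std::log1p(std::exp(m));
    loss += lse - y[i] * m;
  }
  loss /= n;
  double l1 = 0.0, l2 = 0.0;
  for (int j = 0; j < p; ++j) { l1 += std::fabs(w[j]); l2 += w[j] * w[j]; }
  return loss + lam1 * l1 + 0.5 * lam2 * l2;
}

// Stochastic gradient descent for elastic-net logistic regression.
//
// Per-sample update at step t with learning rate eta_t = 1 / (L0 + lam2 * t),
// where L0 bounds the per-sample curvature (0.25 * max ||x_i||^2 + lam2), so
// the schedule starts at a safe 1/L0 and decays at the strong-convexity rate.
// The L2 term enters as multiplicative weight decay; the L1 term uses the
// cumulative-penalty clipping of Tsuruoka et al. (2009), which drives weights
// to exact zero instead of leaving them jittering near it.
//
// perms holds one 0-based visiting order per epoch (drawn under R's RNG so
// fits are reproducible from set.seed()).
// [[Rcpp::export(name = ".sgd_enet_cpp")]]
List sgd_enet_cpp(NumericMatrix Xt, NumericVector y,
                  double alpha, double l1_ratio,
                  int max_epochs, double tol, int patience,
                  IntegerMatrix perms) {
  const int p = Xt.nrow(), n = Xt.ncol();
  if (y.size() != n) stop("length(y) must match sample count");
  const double lam1 = alpha * l1_ratio;
  const double lam2 = alpha * (1.0 - l1_ratio);

  double max_sq = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    const double* xi = &Xt(0, i);
    for (int j = 0; j < p; ++j) s += xi[j] * xi[j];
    if (s > max_sq) max_sq = s;
  }
  const double L0 = 0.25 * max_sq + lam2 + 1e-8;

  std::vector<double> w(p, 0.0), q(p, 0.0);
  double u = 0.0;
  double b = 0.0;
  double t = 0.0;
  double prev_obj = R_PosInf;
  double obj = R_PosInf;
  int stall = 0, epochs_run = 0;

  for (int e = 0; e < max_epochs; ++e) {
    for (int k = 0; k < n; ++k) {
      const int i = perms(e % perms.nrow(), k);
      const double eta = 1.0 / (L0 + lam2 * t);
      double m = b;
      const double* xi = &Xt(0, i);
      for (int j = 0; j < p; ++j) m += w[j] * xi[j];
      const double pr = 1.0 / (1.0 + std::exp(-m));
      const double g = pr - y[i];
      const double decay = 1.0 - eta * lam2;
      u += eta * lam1;
      for (int j = 0; j < p; ++j) {
        const double z = w[j] * decay - eta * g * xi[j];
        double wj = z;
        if (z > 0.0) wj = std::max(0.0, z - (u + q[j]));
        else if (z < 0.0) wj = std::min(0.0, z + (u - q[j]));
        w[j] = wj;
        q[j] += wj - z;
      }
      // the intercept is unpenalized, so its step follows the logistic
      // curvature bound (1/4 per sample) rather than the penalty decay
      b -= g / (1.0 + 0.25 * t);
      t += 1.0;
    }
    ++epochs_run;
    obj = objective(Xt, y, w, b, lam1, lam2);
    if (!std::isfinite(obj))
      stop("non-finite objective during SGD (epoch %d); check feature scaling", epochs_run);
    if (std::fabs(prev_obj - obj) < tol) {
      if (++stall >= patience) { prev_obj = obj; break; }
    } else {
      stall = 0;
    }
    prev_obj = obj;
  }

  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["intercept"] = b,
                      _["objective"] = obj,
                      _["epochs"] = epochs_run);
}

// [[Rcpp::export(name = ".enet_objective_cpp")]]
double enet_objective_cpp(NumericMatrix Xt, NumericVector y,
                          NumericVector w, double b,
                          double alpha, double l1_ratio) {
  std::vector<double> wv(w.begin(), w.end());
  return objective(Xt, y, wv, b, alpha * l1_ratio, alpha * (1.0 - l1_ratio));
}
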
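#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cyclic coordinate descent for the streamline-weight objective
//   J(w, mu) = sum_v ((L w)_v - mu D_v)^2 + lambda * sum_s log(w_s)^2
// over w >= 0, mu > 0.  Each coordinate is minimised exactly (Newton with
// bisection safeguard for the log-penalised scalar problem); mu has a
// closed-form least-squares update.  J is non-increasing by construction.
//
// L is passed in compressed sparse column form (dgCMatrix slots).

static double scalar_objective(double x, double a, double b, double lam) {
  // a x^2 + b x + lam log(x)^2 (quadratic part up to a constant)
  const double lx = std::log(x);
  return a * x * x + b * x + lam * lx * lx;
}

// minimise a x^2 + b x + lam log(x)^2 over x > 0 (a > 0)
static double scalar_min(double a, double b, double lam, double x0) {
  const double lo = 1e-12, hi = 1e12;
  double x = -b / (2.0 * a); // unpenalised minimiser
  if (lam <= 0.0) return x > 0.0 ? x : 0.0;
  if (x < lo) x = std::min(std::max(x0, lo), 1.0);
  // Newton on g(x) = 2 a x + b + 2 lam log(x)/x, safeguarded by bisection
  double l = lo, h = hi;
  for (int it = 0; it < 40; ++it) {
    const double lx = std::log(x);
    const double g = 2.0 * a * x + b + 2.0 * lam * lx / x;
    if (g > 0.0) h = x; else l = x;
    const double gp = 2.0 * a + 2.0 * lam * (1.0 - lx) / (x * x);
    double xn = (gp > 0.0) ? x - g / gp : 0.5 * (l + h);
    if (!(xn > l && xn < h)) xn = 0.5 * (l + h);
    if (std::fabs(xn - x) < 1e-12 * std::max(1.0, x)) { x = xn; break; }
    x = xn;
  }
  return x;
}

//' @noRd
// [[Rcpp::export]]
List cpp_fit_weights(IntegerVector Li, IntegerVector Lp, NumericVector Lx,
                     int nrow, int ncol, NumericVector D, double lambda,
                     int max_iters, double tol) {
  std::vector<double> w(ncol, 1.0);
  std::vector<double> colsq(ncol, 0.0);
  for (int s = 0; s < ncol; ++s)
    for (int k = Lp[s]; k < Lp[s + 1]; ++k) colsq[s] += Lx[k] * Lx[k];
  // residual r = L w - mu D
  std::vector<double> Lw(nrow, 0.0);
  for (int s = 0; s < ncol; ++s)
    for (int k = Lp[s]; k < Lp[s + 1]; ++k) Lw[Li[k]] += Lx[k] * w[s];
  double dsum = 0.0, dd = 0.0;
  for (int v = 0; v < nrow; ++v) { dsum += D[v]; dd += D[v] * D[v]; }
  if (dd <= 0.0) stop("density target D is all zero");
  // mu: closed-form mass-matching proportionality at the unit-weight
  // baseline; fixing it removes the (w, mu) -> (c w, c mu) scale
  // degeneracy of the joint least-squares problem
  double lwsum = 0.0;
  for (int v = 0; v < nrow; ++v) lwsum += Lw[v];
  double mu = lwsum / dsum;
  if (mu <= 0.0) mu = 1e-12;
  std::vector<double> r(nrow);
  for (int v = 0; v < nrow; ++v) r[v] = Lw[v] - mu * D[v];
  auto objective = [&]() {
    double J = 0.0;
    for (int v = 0; v < nrow; ++v) J += r[v] * r[v];
    if (lambda > 0.0)
      for (int s = 0; s < ncol; ++s) {
        const double lx = std::log(std::max(w[s], 1e-300));
        J += lambda * lx * lx;
      }
    return J;
  };
  std::vector<double> trace;
  double obj = objective();
  trace.push_back(obj);
  for (int it = 0; it < max_iters; ++it) {
    // one sweep of exact coordinate minimisation
    for (int s = 0; s < ncol; ++s) {
      if (colsq[s] <= 0.0) continue; // streamline outside the support
      double lr = 0.0;
      for (int k = Lp[s]; k < Lp[s + 1]; ++k) lr += Lx[k] * r[Li[k]];
      // J(x) = const + 2 (x - w_s) (L_s . r) + (x - w_s)^2 |L_s|^2
      //        + lambda log(x)^2
      const double a = colsq[s];
      const double b = 2.0 * lr - 2.0 * a * w[s];
      double xn = scalar_min(a, b, lambda, w[s]);
      if (lambda <= 0.0 && xn < 0.0) xn = 0.0;
      const double old_contrib =
          lambda > 0 ? lambda * std::pow(std::log(std::max(w[s], 1e-300)), 2)
                     : 0.0;
      const double new_contrib =
          lambda > 0 ? lambda * std::pow(std::log(std::max(xn, 1e-300)), 2)
                     : 0.0;
      const double dJ = (xn - w[s]) * (2.0 * lr + a * (xn - w[s])) +
                        new_contrib - old_contrib;
      if (dJ >= 0.0) continue; // keep the old value unless it descends
      const double delta = xn - w[s];
      for (int k = Lp[s]; k < Lp[s + 1]; ++k) r[Li[k]] += Lx[k] * delta;
      w[s] = xn;
    }
    const double obj_new = objective();
    trace.push_back(obj_new);
    const bool done = (obj - obj_new) <= tol * std::max(obj, 1e-300);
    obj = obj_new;
    if (done) break;
  }
  return List::create(_["weights"] = wrap(w), _["mu"] = mu,
                      _["objective"] = wrap(trace));
}
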
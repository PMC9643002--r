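#include <Rcpp.h>
#include "sh.h"
using namespace Rcpp;

// Associated Legendre P_l^m without the Condon-Shortley phase, standard
// three-term recurrences.  plm is indexed plm[l * (lmax+1) + m].
static void legendre_table(double ct, int lmax, std::vector<double> &plm) {
  const int n = lmax + 1;
  plm.assign((size_t)n * n, 0.0);
  const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  for (int m = 0; m <= lmax; ++m) {
    double pmm = 1.0;
    for (int k = 1; k <= m; ++k) pmm *= (2.0 * k - 1.0) * st;
    plm[(size_t)m * n + m] = pmm;
    if (m < lmax) plm[(size_t)(m + 1) * n + m] = ct * (2.0 * m + 1.0) * pmm;
    for (int l = m + 2; l <= lmax; ++l)
      plm[(size_t)l * n + m] =
          ((2.0 * l - 1.0) * ct * plm[(size_t)(l - 1) * n + m] -
           (l + m - 1.0) * plm[(size_t)(l - 2) * n + m]) /
          (double)(l - m);
  }
}

void sh_eval_dir(double x, double y, double z, int lmax, double *out) {
  const double ct = z;
  const double phi = std::atan2(y, x);
  const int n = lmax + 1;
  std::vector<double> plm;
  legendre_table(ct, lmax, plm);
  // cos(m phi), sin(m phi) by recurrence
  std::vector<double> cm(n), sm(n);
  cm[0] = 1.0;
  sm[0] = 0.0;
  const double cp = std::cos(phi), sp = std::sin(phi);
  for (int m = 1; m <= lmax; ++m) {
    cm[m] = cm[m - 1] * cp - sm[m - 1] * sp;
    sm[m] = sm[m - 1] * cp + cm[m - 1] * sp;
  }
  const double sqrt2 = std::sqrt(2.0);
  int idx = 0;
  for (int l = 0; l <= lmax; l += 2) {
    for (int m = -l; m <= l; ++m) {
      const int am = m < 0 ? -m : m;
      const double N = std::sqrt((2.0 * l + 1.0) / (4.0 * M_PI) *
                                 std::exp(std::lgamma(l - am + 1.0) -
                                          std::lgamma(l + am + 1.0)));
      const double p = plm[(size_t)l * n + am];
      double v;
      if (m == 0)
        v = N * p;
      else if (m > 0)
        v = sqrt2 * N * p * cm[am];
      else
        v = sqrt2 * N * p * sm[am];
      out[idx++] = v;
    }
  }
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_sh_basis(NumericMatrix dirs, int lmax) {
  if (lmax < 0 || lmax % 2 != 0) stop("lmax must be a non-negative even integer");
  const int n = dirs.nrow();
  const int nc = sh_ncoef(lmax);
  NumericMatrix out(n, nc);
  std::vector<double> row(nc);
  for (int i = 0; i < n; ++i) {
    sh_eval_dir(dirs(i, 0), dirs(i, 1), dirs(i, 2), lmax, row.data());
    for (int c = 0; c < nc; ++c) out(i, c) = row[c];
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericMatrix u) {
  if (dim.size() != 4) stop("dim must have length 4");
  const int nx = dim[0], ny = dim[1], nz = dim[2], nc = dim[3];
  if ((long)nx * ny * nz * nc != (long)vol.size())
    stop("volume size does not match dim");
  const int n = u.nrow();
  NumericMatrix out(n, nc);
  std::vector<double> buf(nc);
  for (int i = 0; i < n; ++i) {
    trilinear_channels(REAL(vol), nx, ny, nz, nc, u(i, 0), u(i, 1), u(i, 2),
                       buf.data());
    for (int c = 0; c < nc; ++c) out(i, c) = buf[c];
  }
  return out;
}
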
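#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include "sh.h"
using namespace Rcpp;

// Exact polyline-voxel traversal.  Points are mapped to continuous voxel
// indices with the world->voxel 3x4 transform; voxel v occupies the
// half-open cube [v - 0.5, v + 0.5) in continuous index space (centres at
// integers, containment by floor(u + 0.5)).

static inline void w2v(const double *M, const double *p, double *u) {
  for (int r = 0; r < 3; ++r)
    u[r] = M[4 * r] * p[0] + M[4 * r + 1] * p[1] + M[4 * r + 2] * p[2] +
           M[4 * r + 3] + 0.5; // shifted: voxel v spans [v, v+1)
}

// accumulate length of one segment (world-mm length wlen) into cells
static void walk_segment(const double *u0, const double *u1, double wlen,
                         int nx, int ny, int nz,
                         std::unordered_map<long, double> &acc) {
  std::vector<double> ts;
  ts.push_back(0.0);
  for (int ax = 0; ax < 3; ++ax) {
    const double a = u0[ax], b = u1[ax];
    if (a == b) continue;
    const int lo = (int)std::floor(std::min(a, b)) + 1;
    const int hi = (int)std::floor(std::max(a, b));
    for (int c = lo; c <= hi; ++c) {
      const double t = (c - a) / (b - a);
      if (t > 0.0 && t < 1.0) ts.push_back(t);
    }
  }
  ts.push_back(1.0);
  std::sort(ts.begin(), ts.end());
  const long nxy = (long)nx * ny;
  for (size_t i = 0; i + 1 < ts.size(); ++i) {
    const double t0 = ts[i], t1 = ts[i + 1];
    if (t1 <= t0) continue;
    const double tm = 0.5 * (t0 + t1);
    const int ix = (int)std::floor(u0[0] + tm * (u1[0] - u0[0]));
    const int iy = (int)std::floor(u0[1] + tm * (u1[1] - u0[1]));
    const int iz = (int)std::floor(u0[2] + tm * (u1[2] - u0[2]));
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
      continue;
    acc[ix + nx * (long)iy + nxy * iz] += (t1 - t0) * wlen;
  }
}

static void streamline_cells(NumericMatrix pts, const double *M, int nx,
                             int ny, int nz,
                             std::unordered_map<long, double> &acc) {
  acc.clear();
  const int np = pts.nrow();
  if (np < 2) return;
  double u0[3], u1[3], p0[3], p1[3];
  for (int k = 0; k < 3; ++k) p0[k] = pts(0, k);
  w2v(M, p0, u0);
  for (int i = 1; i < np; ++i) {
    for (int k = 0; k < 3; ++k) p1[k] = pts(i, k);
    w2v(M, p1, u1);
    const double dx = p1[0] - p0[0], dy = p1[1] - p0[1], dz = p1[2] - p0[2];
    const double wlen = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (wlen > 0.0) walk_segment(u0, u1, wlen, nx, ny, nz, acc);
    for (int k = 0; k < 3; ++k) { p0[k] = p1[k]; u0[k] = u1[k]; }
  }
}

//' Per-voxel traversal lengths of every streamline (sparse triplets)
//' @noRd
// [[Rcpp::export]]
List cpp_voxel_lengths(List streamlines, NumericMatrix world2vox34,
                       IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  double M[12];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 4; ++c) M[4 * r + c] = world2vox34(r, c);
  std::vector<int> vi, si;
  std::vector<double> len;
  std::unordered_map<long, double> acc;
  const int n = streamlines.size();
  for (int s = 0; s < n; ++s) {
    NumericMatrix pts = streamlines[s];
    streamline_cells(pts, M, nx, ny, nz, acc);
    for (auto &kv : acc) {
      vi.push_back((int)kv.first + 1); // 1-based linear voxel index
      si.push_back(s + 1);
      len.push_back(kv.second);
    }
  }
  return List::create(_["voxel"] = wrap(vi), _["streamline"] = wrap(si),
                      _["length"] = wrap(len));
}

//' Track-density map: each voxel counts each traversing streamline once
//' (optionally weighted).
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_tdi(List streamlines, NumericMatrix world2vox34,
                      IntegerVector dim, NumericVector weights) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  double M[12];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 4; ++c) M[4 * r + c] = world2vox34(r, c);
  NumericVector out((long)nx * ny * nz);
  std::unordered_map<long, double> acc;
  const int n = streamlines.size();
  const bool hw = weights.size() == n;
  for (int s = 0; s < n; ++s) {
    NumericMatrix pts = streamlines[s];
    streamline_cells(pts, M, nx, ny, nz, acc);
    const double w = hw ? weights[s] : 1.0;
    for (auto &kv : acc)
      if (kv.second > 0.0) out[kv.first] += w;
  }
  return out;
}
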
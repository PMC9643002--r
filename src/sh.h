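#pragma once
#include <cmath>
#include <vector>

// Real, symmetric (even-order) spherical-harmonic basis.
// Coefficient ordering follows the MRtrix convention:
//   l = 0, 2, ..., lmax; within each l, m = -l, ..., 0, ..., +l.
// Basis functions (orthonormal on the sphere):
//   m == 0 : N(l,0)  P_l^0(cos th)
//   m  > 0 : sqrt(2) N(l,m)  P_l^m(cos th) cos(m phi)
//   m  < 0 : sqrt(2) N(l,|m|) P_l^|m|(cos th) sin(|m| phi)
// with N(l,m) = sqrt((2l+1)/(4 pi) * (l-m)!/(l+m)!)

inline int sh_ncoef(int lmax) { return (lmax + 1) * (lmax + 2) / 2; }

void sh_eval_dir(double x, double y, double z, int lmax, double *out);

// Sum over even l <= lmax of (2l+1)/(4 pi): bound on sum of squared basis
// values at any direction (addition theorem); used for rejection-sampling
// envelopes.
inline double sh_sumsq_bound(int lmax) {
  double s = 0.0;
  for (int l = 0; l <= lmax; l += 2) s += (2.0 * l + 1.0);
  return s / (4.0 * M_PI);
}

// Trilinear interpolation of a channel-last 4-D volume (column-major,
// dims nx,ny,nz,nc) at a continuous 0-based voxel index (centres at
// integers).  Values outside the array are treated as zero.
inline void trilinear_channels(const double *vol, int nx, int ny, int nz,
                               int nc, double ux, double uy, double uz,
                               double *out) {
  for (int c = 0; c < nc; ++c) out[c] = 0.0;
  const int i0 = (int)std::floor(ux), j0 = (int)std::floor(uy),
            k0 = (int)std::floor(uz);
  const double fx = ux - i0, fy = uy - j0, fz = uz - k0;
  const long nxy = (long)nx * ny, nxyz = nxy * nz;
  for (int dk = 0; dk < 2; ++dk) {
    const int k = k0 + dk;
    if (k < 0 || k >= nz) continue;
    const double wz = dk ? fz : 1.0 - fz;
    for (int dj = 0; dj < 2; ++dj) {
      const int j = j0 + dj;
      if (j < 0 || j >= ny) continue;
      const double wy = dj ? fy : 1.0 - fy;
      for (int di = 0; di < 2; ++di) {
        const int i = i0 + di;
        if (i < 0 || i >= nx) continue;
        const double w = wz * wy * (di ? fx : 1.0 - fx);
        if (w == 0.0) continue;
        const long base = i + (long)nx * j + nxy * k;
        for (int c = 0; c < nc; ++c) out[c] += w * vol[base + nxyz * c];
      }
    }
  }
}
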
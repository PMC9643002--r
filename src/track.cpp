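#include <Rcpp.h>
#include "sh.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Probabilistic streamline tractography under anatomically-constrained
// (5TT) priors.  First-order rejection sampling of directions within an
// angular cone of the previous direction; bidirectional propagation from
// each seed; optional backtracking (truncate + resample) on rejection
// events.  All randomness comes from R's RNG (unif_rand), so runs are
// reproducible via set.seed().
// ---------------------------------------------------------------------------

// tissue states
enum { ST_WM = 0, ST_CGM = 1, ST_SGM = 2, ST_CSF = 3, ST_NP = 4, ST_OUT = 5 };
// arm termination codes
enum {
  ARM_GM = 0,     // entered (sub)cortical GM: accepted endpoint
  ARM_NP_END = 1, // propagation ended inside no-priors tissue: accepted
  ARM_EXIT = 2,   // left the field of view / hit the step cap
  ARM_CSF = 3,    // entered CSF (irrecoverable)
  ARM_NOPROP = 4  // propagation failed in WM (irrecoverable)
};
// streamline statuses (order matches R side)
enum {
  STA_ACCEPT = 0,
  STA_SHORT = 1,
  STA_LONG = 2,
  STA_CSF = 3,
  STA_NOPROP = 4
};

struct Field {
  const double *fod;
  int fx, fy, fz, fc; // fod dims, fc = n coefficients
  const double *t5;
  int tx, ty, tz; // 5 channels assumed
  double M[12];   // world -> continuous voxel index (3x4, row-major)
  double A[12];   // voxel index -> world (3x4, row-major)
  int lmax;
};

static inline void world2vox(const Field &f, const double *p, double *u) {
  for (int r = 0; r < 3; ++r)
    u[r] = f.M[4 * r] * p[0] + f.M[4 * r + 1] * p[1] + f.M[4 * r + 2] * p[2] +
           f.M[4 * r + 3];
}

static inline void vox2world(const Field &f, const double *u, double *p) {
  for (int r = 0; r < 3; ++r)
    p[r] = f.A[4 * r] * u[0] + f.A[4 * r + 1] * u[1] + f.A[4 * r + 2] * u[2] +
           f.A[4 * r + 3];
}

// classify the interpolated 5TT vector; argmax with the documented
// precedence WM > cortical GM > subcortical GM > no-priors > CSF
static int classify5(const double *v) {
  const double s = v[0] + v[1] + v[2] + v[3] + v[4];
  if (s <= 0.5) return ST_OUT;
  static const int chan[5] = {2, 0, 1, 4, 3}; // precedence order (channel idx)
  static const int state[5] = {ST_WM, ST_CGM, ST_SGM, ST_NP, ST_CSF};
  int best = 0;
  double bv = v[chan[0]];
  for (int i = 1; i < 5; ++i)
    if (v[chan[i]] > bv) {
      bv = v[chan[i]];
      best = i;
    }
  return state[best];
}

static inline int tissue_at(const Field &f, const double *p, double *v5) {
  double u[3];
  world2vox(f, p, u);
  trilinear_channels(f.t5, f.tx, f.ty, f.tz, 5, u[0], u[1], u[2], v5);
  return classify5(v5);
}

static inline void fod_at(const Field &f, const double *p, double *coef) {
  double u[3];
  world2vox(f, p, u);
  trilinear_channels(f.fod, f.fx, f.fy, f.fz, f.fc, u[0], u[1], u[2], coef);
}

struct Params {
  double step, cos_max_angle, cutoff, min_len, max_len;
  int max_trials, trunc_depth, retries;
  bool backtrack;
  int max_steps; // per-arm cap derived from max_len
};

// sample a direction within the cone of half-angle acos(cos_min) around
// prev (cos_min = -1 gives the full sphere); rejection sampling against
// the FOD amplitude with envelope amax.  Returns true on success.
static bool sample_dir(const Field &f, const double *coef, const double *prev,
                       double cos_min, const Params &par, double *out) {
  // envelope from coefficient norm and the basis addition theorem
  double cn2 = 0.0;
  for (int c = 0; c < f.fc; ++c) cn2 += coef[c] * coef[c];
  const double amax = std::sqrt(cn2 * sh_sumsq_bound(f.lmax));
  if (amax < par.cutoff) return false;
  // orthonormal frame around prev
  double e1[3], e2[3];
  if (std::fabs(prev[0]) < 0.9) {
    e1[0] = 0.0; e1[1] = -prev[2]; e1[2] = prev[1];
  } else {
    e1[0] = -prev[2]; e1[1] = 0.0; e1[2] = prev[0];
  }
  double n1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
  for (int k = 0; k < 3; ++k) e1[k] /= n1;
  e2[0] = prev[1] * e1[2] - prev[2] * e1[1];
  e2[1] = prev[2] * e1[0] - prev[0] * e1[2];
  e2[2] = prev[0] * e1[1] - prev[1] * e1[0];
  std::vector<double> basis(f.fc);
  for (int t = 0; t < par.max_trials; ++t) {
    const double zc = 1.0 - unif_rand() * (1.0 - cos_min);
    const double ph = 2.0 * M_PI * unif_rand();
    const double sc = std::sqrt(std::max(0.0, 1.0 - zc * zc));
    double d[3];
    for (int k = 0; k < 3; ++k)
      d[k] = zc * prev[k] + sc * (std::cos(ph) * e1[k] + std::sin(ph) * e2[k]);
    sh_eval_dir(d[0], d[1], d[2], f.lmax, basis.data());
    double amp = 0.0;
    for (int c = 0; c < f.fc; ++c) amp += basis[c] * coef[c];
    if (amp < par.cutoff) continue;
    if (unif_rand() * amax <= amp) {
      for (int k = 0; k < 3; ++k) out[k] = d[k];
      return true;
    }
  }
  return false;
}

struct Arm {
  std::vector<double> pts;  // 3 per point
  std::vector<double> dirs; // direction used to arrive at each point
  int code;
};

static void propagate(const Field &f, const Params &par, const double *p0,
                      const double *d0, Arm &arm) {
  arm.pts.assign(p0, p0 + 3);
  arm.dirs.assign(d0, d0 + 3);
  arm.code = ARM_EXIT;
  int retries = par.retries;
  std::vector<double> coef(f.fc);
  double v5[5];
  for (;;) {
    const int np = (int)arm.pts.size() / 3;
    if (np - 1 >= par.max_steps) { arm.code = ARM_EXIT; return; }
    const double *p = &arm.pts[(size_t)(np - 1) * 3];
    const double *d = &arm.dirs[(size_t)(np - 1) * 3];
    fod_at(f, p, coef.data());
    double nd[3];
    const bool ok = sample_dir(f, coef.data(), d, par.cos_max_angle, par, nd);
    int event = -1; // -1 none, 0 csf, 1 noprop
    if (!ok) {
      const int st = tissue_at(f, p, v5);
      if (st == ST_NP) { arm.code = ARM_NP_END; return; }
      event = 1;
    } else {
      double q[3];
      for (int k = 0; k < 3; ++k) q[k] = p[k] + par.step * nd[k];
      const int st = tissue_at(f, q, v5);
      if (st == ST_OUT) { arm.code = ARM_EXIT; return; }
      if (st == ST_CSF) {
        event = 0;
      } else if (st == ST_CGM || st == ST_SGM) {
        arm.pts.insert(arm.pts.end(), q, q + 3);
        arm.dirs.insert(arm.dirs.end(), nd, nd + 3);
        arm.code = ARM_GM;
        return;
      } else { // WM or NP: keep going
        arm.pts.insert(arm.pts.end(), q, q + 3);
        arm.dirs.insert(arm.dirs.end(), nd, nd + 3);
        continue;
      }
    }
    // rejection event: backtrack (truncate + resample) if allowed
    if (par.backtrack && retries > 0 && np > 1) {
      --retries;
      const int keep = std::max(1, np - par.trunc_depth);
      arm.pts.resize((size_t)keep * 3);
      arm.dirs.resize((size_t)keep * 3);
      continue;
    }
    arm.code = (event == 0) ? ARM_CSF : ARM_NOPROP;
    return;
  }
}

// Track one streamline from a seed.  init_dir may be NULL (random initial
// direction from the FOD at the seed).  Fills pts (world mm) and returns a
// status code.
static int track_one(const Field &f, const Params &par, const double *seed,
                     const double *init_dir, std::vector<double> &pts) {
  pts.clear();
  double v5[5];
  const int st0 = tissue_at(f, seed, v5);
  if (st0 == ST_OUT) return STA_NOPROP;
  if (st0 == ST_CSF) return STA_CSF;
  if (st0 == ST_CGM || st0 == ST_SGM) return STA_SHORT; // terminates at seed
  double d0[3];
  if (init_dir) {
    for (int k = 0; k < 3; ++k) d0[k] = init_dir[k];
  } else {
    std::vector<double> coef(f.fc);
    fod_at(f, seed, coef.data());
    const double up[3] = {0.0, 0.0, 1.0};
    if (!sample_dir(f, coef.data(), up, -1.0, par, d0)) return STA_NOPROP;
  }
  Arm a1, a2;
  propagate(f, par, seed, d0, a1);
  double d0r[3] = {-d0[0], -d0[1], -d0[2]};
  propagate(f, par, seed, d0r, a2);
  if (a1.code == ARM_CSF || a2.code == ARM_CSF) return STA_CSF;
  if (a1.code == ARM_NOPROP || a2.code == ARM_NOPROP) return STA_NOPROP;
  if (a1.code == ARM_EXIT && a2.code == ARM_EXIT) return STA_NOPROP;
  const int n1 = (int)a1.pts.size() / 3, n2 = (int)a2.pts.size() / 3;
  const int ntot = n1 + n2 - 1;
  const double len = (ntot - 1) * par.step;
  if (len < par.min_len) return STA_SHORT;
  if (len > par.max_len) return STA_LONG;
  pts.reserve((size_t)ntot * 3);
  for (int i = n2 - 1; i >= 1; --i)
    pts.insert(pts.end(), &a2.pts[(size_t)i * 3], &a2.pts[(size_t)i * 3] + 3);
  pts.insert(pts.end(), a1.pts.begin(), a1.pts.end());
  return STA_ACCEPT;
}

static Field make_field(NumericVector fod, IntegerVector fdim,
                        NumericVector t5, IntegerVector tdim,
                        NumericMatrix world2vox34, NumericMatrix vox2world34,
                        int lmax) {
  Field f;
  f.fod = REAL(fod);
  f.fx = fdim[0]; f.fy = fdim[1]; f.fz = fdim[2]; f.fc = fdim[3];
  f.t5 = REAL(t5);
  f.tx = tdim[0]; f.ty = tdim[1]; f.tz = tdim[2];
  if (tdim[3] != 5) stop("tissue volume must have 5 channels");
  if (f.fc != sh_ncoef(lmax)) stop("FOD channel count does not match lmax");
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 4; ++c) {
      f.M[4 * r + c] = world2vox34(r, c);
      f.A[4 * r + c] = vox2world34(r, c);
    }
  f.lmax = lmax;
  return f;
}

static Params make_params(List par) {
  Params p;
  p.step = as<double>(par["step"]);
  p.cos_max_angle = std::cos(as<double>(par["max_angle"]) * M_PI / 180.0);
  p.cutoff = as<double>(par["fod_cutoff"]);
  p.min_len = as<double>(par["min_length"]);
  p.max_len = as<double>(par["max_length"]);
  p.max_trials = as<int>(par["max_trials"]);
  p.trunc_depth = as<int>(par["trunc_depth"]);
  p.retries = as<int>(par["retries"]);
  p.backtrack = as<bool>(par["backtrack"]);
  p.max_steps = (int)std::ceil(p.max_len / p.step) + 1;
  return p;
}

//' @noRd
// [[Rcpp::export]]
List cpp_generate_tractogram(NumericVector fod, IntegerVector fdim,
                             NumericVector t5, IntegerVector tdim,
                             NumericMatrix world2vox34,
                             NumericMatrix vox2world34, int lmax, List par,
                             int n_target, NumericMatrix seed_voxels,
                             NumericVector seed_cdf, double budget) {
  RNGScope scope;
  Field f = make_field(fod, fdim, t5, tdim, world2vox34, vox2world34, lmax);
  Params pp = make_params(par);
  const int nseed = seed_voxels.nrow();
  if (nseed == 0) stop("no seed voxels");
  std::vector<SEXP> keep;
  List out_pts(n_target);
  IntegerVector counts(5);
  double attempts = 0.0;
  int accepted = 0;
  std::vector<double> pts;
  while (accepted < n_target && attempts < budget) {
    attempts += 1.0;
    // draw a seed voxel from the cdf, then a uniform position inside it
    const double r = unif_rand();
    int lo = 0, hi = nseed - 1;
    while (lo < hi) {
      const int mid = (lo + hi) / 2;
      if (seed_cdf[mid] < r) lo = mid + 1; else hi = mid;
    }
    double u[3], seed[3];
    for (int k = 0; k < 3; ++k)
      u[k] = seed_voxels(lo, k) + (unif_rand() - 0.5);
    vox2world(f, u, seed);
    const int sta = track_one(f, pp, seed, nullptr, pts);
    counts[sta]++;
    if (sta == STA_ACCEPT) {
      const int np = (int)pts.size() / 3;
      NumericMatrix m(np, 3);
      for (int i = 0; i < np; ++i)
        for (int k = 0; k < 3; ++k) m(i, k) = pts[(size_t)i * 3 + k];
      out_pts[accepted++] = m;
    }
  }
  if (accepted < n_target) {
    List trimmed(accepted);
    for (int i = 0; i < accepted; ++i) trimmed[i] = out_pts[i];
    out_pts = trimmed;
  }
  return List::create(_["streamlines"] = out_pts, _["counts"] = counts,
                      _["attempts"] = attempts,
                      _["budget_exhausted"] = accepted < n_target);
}

//' @noRd
// [[Rcpp::export]]
List cpp_track_seeds(NumericVector fod, IntegerVector fdim, NumericVector t5,
                     IntegerVector tdim, NumericMatrix world2vox34,
                     NumericMatrix vox2world34, int lmax, List par,
                     NumericMatrix seeds, Nullable<NumericMatrix> init_dirs) {
  RNGScope scope;
  Field f = make_field(fod, fdim, t5, tdim, world2vox34, vox2world34, lmax);
  Params pp = make_params(par);
  const int n = seeds.nrow();
  List out_pts(n);
  IntegerVector status(n);
  NumericMatrix idirs;
  bool have_dirs = init_dirs.isNotNull();
  if (have_dirs) idirs = NumericMatrix(init_dirs);
  std::vector<double> pts;
  for (int i = 0; i < n; ++i) {
    double s[3] = {seeds(i, 0), seeds(i, 1), seeds(i, 2)};
    double d[3];
    const double *dp = nullptr;
    if (have_dirs) {
      for (int k = 0; k < 3; ++k) d[k] = idirs(i, k);
      dp = d;
    }
    status[i] = track_one(f, pp, s, dp, pts);
    const int np = (int)pts.size() / 3;
    NumericMatrix m(np, 3);
    for (int j = 0; j < np; ++j)
      for (int k = 0; k < 3; ++k) m(j, k) = pts[(size_t)j * 3 + k];
    out_pts[i] = m;
  }
  return List::create(_["streamlines"] = out_pts, _["status"] = status);
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_sample_direction(NumericVector coef, int lmax,
                                   NumericVector prev, double max_angle_deg,
                                   double cutoff, int max_trials) {
  RNGScope scope;
  Field f;
  f.fc = coef.size();
  f.lmax = lmax;
  if (f.fc != sh_ncoef(lmax)) stop("coefficient length does not match lmax");
  Params pp;
  pp.cutoff = cutoff;
  pp.max_trials = max_trials;
  pp.cos_max_angle = std::cos(max_angle_deg * M_PI / 180.0);
  double d[3];
  const double p[3] = {prev[0], prev[1], prev[2]};
  if (!sample_dir(f, REAL(coef), p, pp.cos_max_angle, pp, d))
    return NumericVector(0);
  return NumericVector::create(d[0], d[1], d[2]);
}
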
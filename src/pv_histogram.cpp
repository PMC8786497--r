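#include <Rcpp.h>
using namespace Rcpp;

// Locate a fractional grid coordinate g on an axis of n voxels.
// On success sets the lower cell index i0 and the fractional offset frac
// (the weight of the upper neighbour) and returns true.  The top edge
// g = n-1 is kept (i0 = n-2, frac = 1) and an axis of a single voxel
// accepts only g ~ 0, so out-of-grid points are rejected, never clamped.
static inline bool axis_cell(const double g, const int n, int& i0,
                             double& frac) {
  const double eps = 1e-9;
  if (n == 1) {
    if (std::fabs(g) > eps) return false;
    i0 = 0;
    frac = 0.0;
    return true;
  }
  if (g < -eps || g > (double)(n - 1) + eps) return false;
  i0 = (int)std::floor(g);
  if (i0 < 0) i0 = 0;
  if (i0 > n - 2) i0 = n - 2;
  frac = g - i0;
  if (frac < 0.0) frac = 0.0;
  if (frac > 1.0) frac = 1.0;
  return true;
}

// Partial-volume accumulation of a joint histogram.
//
// For each sampled reference voxel the corresponding floating-space location
// is computed through the inverse rigid map w -> Rinv * w + tinv (reference
// world mm -> floating world mm).  The eight floating-grid neighbours of that
// location receive their trilinear weights as fractional counts in the row of
// the reference voxel's intensity bin.  A sample falling outside the floating
// grid contributes nothing and is excluded from n_samples, so the per-sample
// weights of every counted sample sum to one.
//
// ref_bin   : 0-based intensity bin per sample (length N)
// ref_world : N x 3 world coordinates (mm) of the samples in the reference
//             centre-of-gravity frame
// flt_bin   : 0-based intensity bin per floating voxel, flattened in R's
//             column-major order with dims flt_dim
// flt_voxel : floating voxel size (mm); flt_cog: floating centre of gravity
//             in fractional 0-based voxel indices
// [[Rcpp::export]]
List pv_accumulate(const IntegerVector& ref_bin,
                   const NumericMatrix& ref_world,
                   const IntegerVector& flt_bin,
                   const IntegerVector& flt_dim,
                   const NumericVector& flt_voxel,
                   const NumericVector& flt_cog,
                   const NumericMatrix& Rinv,
                   const NumericVector& tinv,
                   const int bins_ref,
                   const int bins_flt) {
  const int n = ref_bin.size();
  const int nx = flt_dim[0], ny = flt_dim[1], nz = flt_dim[2];
  NumericMatrix counts(bins_ref, bins_flt);
  long long n_samples = 0;

  const double r00 = Rinv(0, 0), r01 = Rinv(0, 1), r02 = Rinv(0, 2);
  const double r10 = Rinv(1, 0), r11 = Rinv(1, 1), r12 = Rinv(1, 2);
  const double r20 = Rinv(2, 0), r21 = Rinv(2, 1), r22 = Rinv(2, 2);

  for (int s = 0; s < n; ++s) {
    const double wx = ref_world(s, 0), wy = ref_world(s, 1),
                 wz = ref_world(s, 2);
    // floating world (mm), then fractional voxel index
    const double fx = r00 * wx + r01 * wy + r02 * wz + tinv[0];
    const double fy = r10 * wx + r11 * wy + r12 * wz + tinv[1];
    const double fz = r20 * wx + r21 * wy + r22 * wz + tinv[2];

    int i0, j0, k0;
    double dx, dy, dz;
    if (!axis_cell(fx / flt_voxel[0] + flt_cog[0], nx, i0, dx)) continue;
    if (!axis_cell(fy / flt_voxel[1] + flt_cog[1], ny, j0, dy)) continue;
    if (!axis_cell(fz / flt_voxel[2] + flt_cog[2], nz, k0, dz)) continue;

    const double wxs[2] = {1.0 - dx, dx};
    const double wys[2] = {1.0 - dy, dy};
    const double wzs[2] = {1.0 - dz, dz};

    const int row = ref_bin[s];
    for (int c = 0; c < 2; ++c) {
      for (int b = 0; b < 2; ++b) {
        for (int a = 0; a < 2; ++a) {
          const double w = wxs[a] * wys[b] * wzs[c];
          if (w == 0.0) continue;
          const R_xlen_t idx = (R_xlen_t)(i0 + a) +
                               (R_xlen_t)nx * ((R_xlen_t)(j0 + b) +
                                               (R_xlen_t)ny * (k0 + c));
          counts(row, flt_bin[idx]) += w;
        }
      }
    }
    ++n_samples;
  }

  return List::create(_["counts"] = counts,
                      _["n_samples"] = (double)n_samples);
}

// Trilinear interpolation of a volume at fractional voxel coordinates.
// Points outside the grid get `fill`.
// [[Rcpp::export]]
NumericVector trilinear_sample(const NumericVector& vol,
                               const IntegerVector& dim,
                               const NumericMatrix& coords,
                               const double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);

  for (R_xlen_t s = 0; s < n; ++s) {
    int i0, j0, k0;
    double dx, dy, dz;
    if (!axis_cell(coords(s, 0), nx, i0, dx) ||
        !axis_cell(coords(s, 1), ny, j0, dy) ||
        !axis_cell(coords(s, 2), nz, k0, dz)) {
      out[s] = fill;
      continue;
    }
    double acc = 0.0;
    const double wxs[2] = {1.0 - dx, dx};
    const double wys[2] = {1.0 - dy, dy};
    const double wzs[2] = {1.0 - dz, dz};
    for (int c = 0; c < 2; ++c)
      for (int b = 0; b < 2; ++b)
        for (int a = 0; a < 2; ++a) {
          const double w = wxs[a] * wys[b] * wzs[c];
          if (w == 0.0) continue;
          const R_xlen_t idx = (R_xlen_t)(i0 + a) +
                               (R_xlen_t)nx * ((R_xlen_t)(j0 + b) +
                                               (R_xlen_t)ny * (k0 + c));
          acc += w * vol[idx];
        }
    out[s] = acc;
  }
  return out;
}
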
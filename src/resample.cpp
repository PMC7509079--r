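#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation of a 3-D volume at arbitrary continuous voxel
// coordinates (0-based). Points outside the grid return `fill`.
static inline double interp_one(const double* v,
                                int nx, int ny, int nz,
                                double x, double y, double z,
                                double fill) {
  // tolerate round-off at the grid boundary before declaring out-of-bounds
  const double eps = 1e-6;
  if (x < -eps || y < -eps || z < -eps ||
      x > nx - 1 + eps || y > ny - 1 + eps || z > nz - 1 + eps) return fill;
  if (x < 0) x = 0;
  if (y < 0) y = 0;
  if (z < 0) z = 0;
  if (x > nx - 1) x = nx - 1;
  if (y > ny - 1) y = ny - 1;
  if (z > nz - 1) z = nz - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const double* p = v + x0 * sx + (R_xlen_t)y0 * sy + (R_xlen_t)z0 * sz;
  double c00 = p[0]      * (1 - fx) + p[sx]           * fx;
  double c10 = p[sy]     * (1 - fx) + p[sy + sx]      * fx;
  double c01 = p[sz]     * (1 - fx) + p[sz + sx]      * fx;
  double c11 = p[sy + sz]* (1 - fx) + p[sy + sz + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export(name = ".interp_trilinear")]]
NumericVector interp_trilinear(NumericVector vol, IntegerVector dim,
                               NumericMatrix pts, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double* v = REAL(vol);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = interp_one(v, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2), fill);
  return out;
}

// Resample a volume through an affine map in continuous voxel coordinates:
// source_coord = M[,1:3] %*% out_coord + M[,4], out_coord 0-based.
// [[Rcpp::export(name = ".resample_affine")]]
NumericVector resample_affine(NumericVector vol, IntegerVector dim,
                              IntegerVector dim_out, NumericMatrix M,
                              double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = dim_out[0], oy = dim_out[1], oz = dim_out[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* v = REAL(vol);
  double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j) {
      double bx = m01 * j + m02 * k + m03;
      double by = m11 * j + m12 * k + m13;
      double bz = m21 * j + m22 * k + m23;
      for (int i = 0; i < ox; ++i, ++idx)
        out[idx] = interp_one(v, nx, ny, nz,
                              m00 * i + bx, m10 * i + by, m20 * i + bz, fill);
    }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}
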
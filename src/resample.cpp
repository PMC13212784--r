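#include <Rcpp.h>
using namespace Rcpp;

static inline double sample_trilinear(const double *v, int nx, int ny, int nz,
                                      double x, double y, double z, double fill) {
  // positions up to half a voxel beyond the first/last sample are clamped
  // (still inside the physical extent); anything further is background
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5)
    return fill;
  if (x < 0.0) x = 0.0;
  if (y < 0.0) y = 0.0;
  if (z < 0.0) z = 0.0;
  if (x > nx - 1.0) x = nx - 1.0;
  if (y > ny - 1.0) y = ny - 1.0;
  if (z > nz - 1.0) z = nz - 1.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1), z1 = std::min(z0 + 1, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const size_t sxy = (size_t)nx * ny;
#define V(i, j, k) v[(size_t)(i) + (size_t)nx * (j) + sxy * (k)]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
#undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double sample_nearest(const double *v, int nx, int ny, int nz,
                                    double x, double y, double z, double fill) {
  int i = (int)std::floor(x + 0.5), j = (int)std::floor(y + 0.5), k = (int)std::floor(z + 0.5);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return fill;
  return v[(size_t)i + (size_t)nx * j + (size_t)nx * ny * k];
}

// Resample `vol` (grid: dim_in/spacing_in/origin_in) onto an output grid.
// M, t map output-grid world coordinates into input-grid world coordinates.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector vol, IntegerVector dim_in,
                                  IntegerVector dim_out, NumericMatrix M,
                                  NumericVector t, NumericVector spacing_in,
                                  NumericVector origin_in, NumericVector spacing_out,
                                  NumericVector origin_out, bool linear, double fill) {
  int nx = dim_in[0], ny = dim_in[1], nz = dim_in[2];
  int ox = dim_out[0], oy = dim_out[1], oz = dim_out[2];
  NumericVector out((size_t)ox * oy * oz);
  const double *v = vol.begin();
  size_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    double wz = origin_out[2] + k * spacing_out[2];
    for (int j = 0; j < oy; ++j) {
      double wy = origin_out[1] + j * spacing_out[1];
      for (int i = 0; i < ox; ++i, ++idx) {
        double wx = origin_out[0] + i * spacing_out[0];
        double px = M(0, 0) * wx + M(0, 1) * wy + M(0, 2) * wz + t[0];
        double py = M(1, 0) * wx + M(1, 1) * wy + M(1, 2) * wz + t[1];
        double pz = M(2, 0) * wx + M(2, 1) * wy + M(2, 2) * wz + t[2];
        double x = (px - origin_in[0]) / spacing_in[0];
        double y = (py - origin_in[1]) / spacing_in[1];
        double z = (pz - origin_in[2]) / spacing_in[2];
        out[idx] = linear ? sample_trilinear(v, nx, ny, nz, x, y, z, fill)
                          : sample_nearest(v, nx, ny, nz, x, y, z, fill);
      }
    }
  }
  return out;
}

// Sample `vol` with trilinear interpolation at world points given in the
// fixed frame; M, t map fixed world coordinates into the volume's world
// frame. Points outside the volume give NA.
// [[Rcpp::export]]
NumericVector cpp_sample_points(NumericVector vol, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix M, NumericVector t,
                                NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int np = pts.nrow();
  NumericVector out(np);
  const double *v = vol.begin();
  for (int p = 0; p < np; ++p) {
    double wx = pts(p, 0), wy = pts(p, 1), wz = pts(p, 2);
    double px = M(0, 0) * wx + M(0, 1) * wy + M(0, 2) * wz + t[0];
    double py = M(1, 0) * wx + M(1, 1) * wy + M(1, 2) * wz + t[1];
    double pz = M(2, 0) * wx + M(2, 1) * wy + M(2, 2) * wz + t[2];
    out[p] = sample_trilinear(v, nx, ny, nz,
                              (px - origin[0]) / spacing[0],
                              (py - origin[1]) / spacing[1],
                              (pz - origin[2]) / spacing[2], NA_REAL);
  }
  return out;
}

// Warp a volume by a dense displacement field (mm), same grid in and out:
// out(x) = vol(x + u(x)).
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector vol, IntegerVector dim, NumericVector spacing,
                       NumericVector ux, NumericVector uy, NumericVector uz,
                       bool linear, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  const double *v = vol.begin();
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = i + ux[idx] / spacing[0];
        double y = j + uy[idx] / spacing[1];
        double z = k + uz[idx] / spacing[2];
        out[idx] = linear ? sample_trilinear(v, nx, ny, nz, x, y, z, fill)
                          : sample_nearest(v, nx, ny, nz, x, y, z, fill);
      }
  return out;
}
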
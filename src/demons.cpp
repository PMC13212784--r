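#include <Rcpp.h>
using namespace Rcpp;

NumericVector cpp_gaussian_smooth(NumericVector vol, IntegerVector dim,
                                  NumericVector sigma);
NumericVector cpp_warp(NumericVector vol, IntegerVector dim, NumericVector spacing,
                       NumericVector ux, NumericVector uy, NumericVector uz,
                       bool linear, double fill);

static void central_gradient(const NumericVector &v, const IntegerVector &dim,
                             const NumericVector &spacing, std::vector<double> &gx,
                             std::vector<double> &gy, std::vector<double> &gz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t sxy = (size_t)nx * ny;
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        int ip = std::min(i + 1, nx - 1), im = std::max(i - 1, 0);
        int jp = std::min(j + 1, ny - 1), jm = std::max(j - 1, 0);
        int kp = std::min(k + 1, nz - 1), km = std::max(k - 1, 0);
        gx[idx] = (v[(size_t)ip + (size_t)nx * j + sxy * k] -
                   v[(size_t)im + (size_t)nx * j + sxy * k]) /
                  ((ip - im) * spacing[0]);
        gy[idx] = (v[(size_t)i + (size_t)nx * jp + sxy * k] -
                   v[(size_t)i + (size_t)nx * jm + sxy * k]) /
                  ((jp - jm) * spacing[1]);
        gz[idx] = (v[(size_t)i + (size_t)nx * j + sxy * kp] -
                   v[(size_t)i + (size_t)nx * j + sxy * km]) /
                  ((kp - km) * spacing[2]);
      }
}

// Demons-style iterative deformable registration at a single resolution
// level. The displacement field u (mm) maps fixed-grid voxels to positions
// in the moving image: warped(x) = moving(x + u(x)). Symmetric (average of
// fixed and warped-moving gradients) force, Gaussian field regularisation,
// displacement-magnitude cap, relative-MSE stopping tolerance.
// [[Rcpp::export]]
List cpp_demons(NumericVector fixed, NumericVector moving, IntegerVector dim,
                NumericVector spacing, NumericVector ux0, NumericVector uy0,
                NumericVector uz0, IntegerVector fg, int max_iter,
                double sigma_vox, double max_disp, double tol, double fill) {
  size_t n = (size_t)dim[0] * dim[1] * dim[2];
  NumericVector ux = clone(ux0), uy = clone(uy0), uz = clone(uz0);
  std::vector<double> gfx(n), gfy(n), gfz(n), gwx(n), gwy(n), gwz(n);
  central_gradient(fixed, dim, spacing, gfx, gfy, gfz);
  NumericVector sigma3 = NumericVector::create(sigma_vox, sigma_vox, sigma_vox);

  double mse_prev = R_PosInf, mse0 = NA_REAL, mse = NA_REAL;
  double best_mse = R_PosInf;
  NumericVector bux = clone(ux), buy = clone(uy), buz = clone(uz);
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    NumericVector warped = cpp_warp(moving, dim, spacing, ux, uy, uz, true, fill);
    double sse = 0;
    size_t nfg = 0;
    for (size_t i = 0; i < n; ++i)
      if (fg[i]) {
        double d = warped[i] - fixed[i];
        sse += d * d;
        ++nfg;
      }
    mse = nfg ? sse / nfg : 0.0;
    if (it == 0) mse0 = mse;
    if (mse < best_mse) {
      best_mse = mse;
      bux = clone(ux);
      buy = clone(uy);
      buz = clone(uz);
    }
    if (mse_prev < R_PosInf) {
      double rel = (mse_prev - mse) / std::max(mse_prev, 1e-12);
      if (rel < tol) break;
    }
    mse_prev = mse;

    central_gradient(warped, dim, spacing, gwx, gwy, gwz);
    for (size_t i = 0; i < n; ++i) {
      double diff = warped[i] - fixed[i];
      double gx = 0.5 * (gfx[i] + gwx[i]);
      double gy = 0.5 * (gfy[i] + gwy[i]);
      double gz = 0.5 * (gfz[i] + gwz[i]);
      double g2 = gx * gx + gy * gy + gz * gz;
      double denom = g2 + diff * diff;
      if (denom < 1e-9) continue;
      double f = -diff / denom;
      ux[i] += f * gx;
      uy[i] += f * gy;
      uz[i] += f * gz;
    }
    ux = cpp_gaussian_smooth(ux, dim, sigma3);
    uy = cpp_gaussian_smooth(uy, dim, sigma3);
    uz = cpp_gaussian_smooth(uz, dim, sigma3);
    for (size_t i = 0; i < n; ++i) {
      double m = std::sqrt(ux[i] * ux[i] + uy[i] * uy[i] + uz[i] * uz[i]);
      if (m > max_disp) {
        double s = max_disp / m;
        ux[i] *= s;
        uy[i] *= s;
        uz[i] *= s;
      }
    }
  }
  // return the best iterate, so the metric never worsens versus the
  // initial field
  return List::create(_["ux"] = bux, _["uy"] = buy, _["uz"] = buz,
                      _["iterations"] = it, _["mse_initial"] = mse0,
                      _["mse_final"] = best_mse);
}

// Voxel-wise Jacobian determinant of the mapping x -> x + u(x), u in mm.
// [[Rcpp::export]]
NumericVector cpp_jacobian_det(NumericVector ux, NumericVector uy, NumericVector uz,
                               IntegerVector dim, NumericVector spacing) {
  size_t n = (size_t)dim[0] * dim[1] * dim[2];
  std::vector<double> a11(n), a12(n), a13(n), a21(n), a22(n), a23(n),
      a31(n), a32(n), a33(n);
  central_gradient(ux, dim, spacing, a11, a12, a13);
  central_gradient(uy, dim, spacing, a21, a22, a23);
  central_gradient(uz, dim, spacing, a31, a32, a33);
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) {
    double j11 = 1 + a11[i], j12 = a12[i], j13 = a13[i];
    double j21 = a21[i], j22 = 1 + a22[i], j23 = a23[i];
    double j31 = a31[i], j32 = a32[i], j33 = 1 + a33[i];
    out[i] = j11 * (j22 * j33 - j23 * j32) - j12 * (j21 * j33 - j23 * j31) +
             j13 * (j21 * j32 - j22 * j31);
  }
  return out;
}
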
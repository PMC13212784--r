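#include <Rcpp.h>
using namespace Rcpp;

// Separable Gaussian smoothing with edge-truncated kernel renormalisation.
// sigma in voxel units per axis; sigma <= 0 skips the axis.
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector vol, IntegerVector dim,
                                  NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> buf(vol.begin(), vol.end());
  std::vector<double> tmp(n);
  const int nd[3] = {nx, ny, nz};
  const size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> kern(2 * r + 1);
    for (int d = -r; d <= r; ++d) kern[d + r] = std::exp(-0.5 * d * d / (s * s));
    int len = nd[ax];
    size_t st = stride[ax];
    // iterate over all lines along axis `ax`
    int na = nd[(ax + 1) % 3], nb = nd[(ax + 2) % 3];
    size_t sa = stride[(ax + 1) % 3], sb = stride[(ax + 2) % 3];
    for (int b = 0; b < nb; ++b)
      for (int a = 0; a < na; ++a) {
        size_t base = (size_t)a * sa + (size_t)b * sb;
        for (int i = 0; i < len; ++i) {
          double acc = 0, wsum = 0;
          int lo = std::max(0, i - r), hi = std::min(len - 1, i + r);
          for (int p = lo; p <= hi; ++p) {
            double w = kern[p - i + r];
            acc += w * buf[base + (size_t)p * st];
            wsum += w;
          }
          tmp[base + (size_t)i * st] = acc / wsum;
        }
      }
    buf.swap(tmp);
  }
  return NumericVector(buf.begin(), buf.end());
}

// 3D Sobel gradient magnitude. Along each axis the derivative kernel is
// [-1, 0, 1] combined with [1, 2, 1] smoothing on the two orthogonal axes
// (classic unnormalised Sobel weights). Values outside the volume are zero.
// [[Rcpp::export]]
NumericVector cpp_sobel_magnitude(NumericVector vol, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  const double *v = vol.begin();
  const size_t sxy = (size_t)nx * ny;
  auto at = [&](int i, int j, int k) -> double {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
    return v[(size_t)i + (size_t)nx * j + sxy * k];
  };
  static const int deriv[3] = {-1, 0, 1};
  static const int smooth[3] = {1, 2, 1};
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double g[3] = {0, 0, 0};
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              double val = at(i + di, j + dj, k + dk);
              if (val == 0.0) continue;
              g[0] += deriv[di + 1] * smooth[dj + 1] * smooth[dk + 1] * val;
              g[1] += smooth[di + 1] * deriv[dj + 1] * smooth[dk + 1] * val;
              g[2] += smooth[di + 1] * smooth[dj + 1] * deriv[dk + 1] * val;
            }
        out[idx] = std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
      }
  return out;
}
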
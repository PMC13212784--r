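#include <Rcpp.h>
using namespace Rcpp;

// Sliding-window sums along one axis with zero padding (window truncated at
// the borders); kernel length 2*r+1.
static void window_sum_axis(std::vector<double> &buf, std::vector<double> &tmp,
                            const int nd[3], int ax, int r) {
  const size_t stride[3] = {1, (size_t)nd[0], (size_t)nd[0] * nd[1]};
  int len = nd[ax];
  size_t st = stride[ax];
  int na = nd[(ax + 1) % 3], nb = nd[(ax + 2) % 3];
  size_t sa = stride[(ax + 1) % 3], sb = stride[(ax + 2) % 3];
  for (int b = 0; b < nb; ++b)
    for (int a = 0; a < na; ++a) {
      size_t base = (size_t)a * sa + (size_t)b * sb;
      double acc = 0;
      for (int i = 0; i <= std::min(r, len - 1); ++i) acc += buf[base + (size_t)i * st];
      for (int i = 0; i < len; ++i) {
        tmp[base + (size_t)i * st] = acc;
        int add = i + r + 1, del = i - r;
        if (add < len) acc += buf[base + (size_t)add * st];
        if (del >= 0) acc -= buf[base + (size_t)del * st];
      }
    }
  buf.swap(tmp);
}

// Masked average pooling: for every voxel, the mean of vol over in-mask
// voxels within a centred (2rx+1)x(2ry+1)x(2rz+1) window, plus the in-mask
// count. Outside-volume positions count as out-of-mask (zero padding).
// [[Rcpp::export]]
List cpp_masked_pool(NumericVector vol, IntegerVector mask, IntegerVector dim,
                     int rx, int ry, int rz) {
  const int nd[3] = {dim[0], dim[1], dim[2]};
  size_t n = (size_t)nd[0] * nd[1] * nd[2];
  std::vector<double> sums(n), cnts(n), tmp(n);
  for (size_t i = 0; i < n; ++i) {
    sums[i] = mask[i] ? vol[i] : 0.0;
    cnts[i] = mask[i] ? 1.0 : 0.0;
  }
  const int r[3] = {rx, ry, rz};
  for (int ax = 0; ax < 3; ++ax) {
    window_sum_axis(sums, tmp, nd, ax, r[ax]);
    window_sum_axis(cnts, tmp, nd, ax, r[ax]);
  }
  NumericVector mean_out(n);
  IntegerVector count_out(n);
  for (size_t i = 0; i < n; ++i) {
    double c = cnts[i];
    count_out[i] = (int)(c + 0.5);
    mean_out[i] = c > 0 ? sums[i] / c : NA_REAL;
  }
  return List::create(_["mean"] = mean_out, _["count"] = count_out);
}
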
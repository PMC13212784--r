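#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Connected-component labelling (6 or 26 connectivity) by breadth-first
// search in scan order, so label 1 is the component containing the smallest
// linear voxel index, label 2 the next unvisited one, and so on.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<std::array<int, 3>> offs;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh > 1) continue;
        offs.push_back({di, dj, dk});
      }
  const size_t sxy = (size_t)nx * ny;
  int next_label = 0;
  std::vector<size_t> stack;
  for (size_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || labels[seed]) continue;
    ++next_label;
    labels[seed] = next_label;
    stack.clear();
    stack.push_back(seed);
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      int i = cur % nx, j = (cur / nx) % ny, k = cur / sxy;
      for (auto &o : offs) {
        int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        size_t nb = (size_t)ii + (size_t)nx * jj + sxy * kk;
        if (mask[nb] && !labels[nb]) {
          labels[nb] = next_label;
          stack.push_back(nb);
        }
      }
    }
  }
  return labels;
}

// Binary erosion (all offsets in-mask; outside the volume counts as
// background) or dilation (any offset in-mask) with an arbitrary
// structuring element given as an n x 3 matrix of voxel offsets.
// [[Rcpp::export]]
IntegerVector cpp_binary_morph(IntegerVector mask, IntegerVector dim,
                               IntegerMatrix offsets, bool erode) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  const size_t sxy = (size_t)nx * ny;
  IntegerVector out(n, 0);
  int no = offsets.nrow();
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        if (erode && !mask[idx]) continue;
        bool all_in = true, any_in = false;
        for (int o = 0; o < no; ++o) {
          int ii = i + offsets(o, 0), jj = j + offsets(o, 1), kk = k + offsets(o, 2);
          bool in = false;
          if (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz)
            in = mask[(size_t)ii + (size_t)nx * jj + sxy * kk] != 0;
          if (in) any_in = true; else all_in = false;
          if (erode && !all_in) break;
          if (!erode && any_in) break;
        }
        out[idx] = erode ? (all_in ? 1 : 0) : (any_in ? 1 : 0);
      }
  return out;
}

// Fill background cavities fully enclosed by the mask: background voxels
// not 6-connected to the volume border become foreground.
// [[Rcpp::export]]
IntegerVector cpp_fill_holes(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  const size_t sxy = (size_t)nx * ny;
  std::vector<char> outside(n, 0);
  std::vector<size_t> stack;
  auto push_if_bg = [&](int i, int j, int k) {
    size_t id = (size_t)i + (size_t)nx * j + sxy * k;
    if (!mask[id] && !outside[id]) {
      outside[id] = 1;
      stack.push_back(id);
    }
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 || k == nz - 1)
          push_if_bg(i, j, k);
  static const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!stack.empty()) {
    size_t cur = stack.back();
    stack.pop_back();
    int i = cur % nx, j = (cur / nx) % ny, k = cur / sxy;
    for (auto &o : d6) {
      int ii = i + o[0], jj = j + o[1], kk = k + o[2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      push_if_bg(ii, jj, kk);
    }
  }
  IntegerVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = mask[i] || !outside[i] ? 1 : 0;
  return out;
}
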
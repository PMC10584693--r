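#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Voxel grids are R arrays with dim = (nz, ny, nx); element (z, y, x)
// (1-based in R) lives at linear index (z-1) + nz*((y-1) + ny*(x-1)).

static inline R_xlen_t idx3(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
}

// Separable Gaussian convolution with replicate (nearest) boundary padding,
// kernel truncated at 4 sigma per axis. sigma is (z, y, x) in voxels; an
// axis with sigma <= 0 is left untouched.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur_3d(NumericVector arr, IntegerVector dim,
                                   NumericVector sigma) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n[3] = {nz, ny, nx};
  std::vector<double> src(arr.begin(), arr.end());
  std::vector<double> dst(src.size());

  for (int axis = 0; axis < 3; ++axis) {
    const double s = sigma[axis];
    if (s <= 0) continue;
    const int r = (int)std::ceil(4.0 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0.0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * (double)i * i / (s * s));
      ksum += k[i + r];
    }
    for (double& v : k) v /= ksum;

    const int len = n[axis];
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          const int pos[3] = {z, y, x};
          double acc = 0.0;
          for (int i = -r; i <= r; ++i) {
            int c = pos[axis] + i;
            if (c < 0) c = 0;                 // replicate edge
            if (c >= len) c = len - 1;
            int q[3] = {z, y, x};
            q[axis] = c;
            acc += k[i + r] * src[idx3(q[0], q[1], q[2], nz, ny)];
          }
          dst[idx3(z, y, x, nz, ny)] = acc;
        }
      }
    }
    std::swap(src, dst);
  }
  NumericVector out(src.begin(), src.end());
  out.attr("dim") = dim;
  return out;
}

// 3D local maxima over the 26-neighborhood. A voxel is a candidate if its
// value is finite and >= every in-grid neighbor. Plateaus (26-connected
// candidate components of equal value) are reduced to one representative:
// the lexicographically smallest (z, y, x). Returns 1-based coordinates.
// [[Rcpp::export]]
DataFrame cpp_local_maxima_3d(NumericVector arr, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double* v = arr.begin();
  std::vector<char> cand(arr.size(), 0);

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const double val = v[idx3(z, y, x, nz, ny)];
        if (!R_finite(val)) continue;
        bool ok = true;
        for (int dz = -1; dz <= 1 && ok; ++dz)
          for (int dy = -1; dy <= 1 && ok; ++dy)
            for (int dx = -1; dx <= 1 && ok; ++dx) {
              if (!dz && !dy && !dx) continue;
              const int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                continue;
              if (v[idx3(zz, yy, xx, nz, ny)] > val) ok = false;
            }
        if (ok) cand[idx3(z, y, x, nz, ny)] = 1;
      }

  // plateau reduction: flood over equal-valued candidate neighbors
  std::vector<char> seen(arr.size(), 0);
  std::vector<int> pz, py, px;
  std::vector<double> pv;
  std::vector<R_xlen_t> stack;

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const R_xlen_t i0 = idx3(z, y, x, nz, ny);
        if (!cand[i0] || seen[i0]) continue;
        const double val = v[i0];
        int bz = z, by = y, bx = x;
        stack.clear();
        stack.push_back(i0);
        seen[i0] = 1;
        while (!stack.empty()) {
          const R_xlen_t i = stack.back();
          stack.pop_back();
          const int cx = (int)(i / ((R_xlen_t)nz * ny));
          const int cy = (int)((i / nz) % ny);
          const int cz = (int)(i % nz);
          if (cz < bz || (cz == bz && (cy < by || (cy == by && cx < bx)))) {
            bz = cz; by = cy; bx = cx;
          }
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dz && !dy && !dx) continue;
                const int zz = cz + dz, yy = cy + dy, xx = cx + dx;
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                  continue;
                const R_xlen_t j = idx3(zz, yy, xx, nz, ny);
                if (cand[j] && !seen[j] && v[j] == val) {
                  seen[j] = 1;
                  stack.push_back(j);
                }
              }
        }
        pz.push_back(bz + 1); py.push_back(by + 1); px.push_back(bx + 1);
        pv.push_back(val);
      }

  return DataFrame::create(_["z"] = wrap(pz), _["y"] = wrap(py),
                           _["x"] = wrap(px), _["intensity"] = wrap(pv));
}

// Connected-component labeling of a boolean grid, 26-connectivity.
// Returns an integer array of labels (0 = background) plus attribute
// "n_components".
// [[Rcpp::export]]
IntegerVector cpp_label_components_3d(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int* m = mask.begin();
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<R_xlen_t> stack;

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const R_xlen_t i0 = idx3(z, y, x, nz, ny);
        if (!m[i0] || lab[i0]) continue;
        ++next;
        stack.clear();
        stack.push_back(i0);
        lab[i0] = next;
        while (!stack.empty()) {
          const R_xlen_t i = stack.back();
          stack.pop_back();
          const int cx = (int)(i / ((R_xlen_t)nz * ny));
          const int cy = (int)((i / nz) % ny);
          const int cz = (int)(i % nz);
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dz && !dy && !dx) continue;
                const int zz = cz + dz, yy = cy + dy, xx = cx + dx;
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                  continue;
                const R_xlen_t j = idx3(zz, yy, xx, nz, ny);
                if (m[j] && !lab[j]) {
                  lab[j] = next;
                  stack.push_back(j);
                }
              }
        }
      }

  lab.attr("dim") = dim;
  lab.attr("n_components") = next;
  return lab;
}
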
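// 3D image kernels: separable Gaussian smoothing, 26-connected component
// labelling, and an exact anisotropic squared Euclidean distance transform
// (Felzenszwalb-Huttenlocher lower-envelope algorithm, one pass per axis).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_gauss_blur3(NumericVector img, IntegerVector dim,
                              NumericVector sigma) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  size_t ntot = (size_t)d1 * d2 * d3;
  std::vector<double> a(img.begin(), img.end()), b(ntot);

  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int hw = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * hw + 1);
    double sum = 0;
    for (int i = -hw; i <= hw; ++i) {
      k[i + hw] = std::exp(-0.5 * i * i / (s * s));
      sum += k[i + hw];
    }
    for (double& v : k) v /= sum;

    int len = axis == 0 ? d1 : (axis == 1 ? d2 : d3);
    size_t stride = axis == 0 ? 1 : (axis == 1 ? (size_t)d1 : (size_t)d1 * d2);
    // iterate all lines along `axis`
    int n_other1 = axis == 0 ? d2 : d1;
    int n_other2 = axis == 2 ? d2 : d3;
    size_t so1 = axis == 0 ? (size_t)d1 : 1;
    size_t so2 = axis == 2 ? (size_t)d1 : (size_t)d1 * d2;
    for (int u = 0; u < n_other1; ++u) {
      for (int v = 0; v < n_other2; ++v) {
        size_t base = (size_t)u * so1 + (size_t)v * so2;
        for (int i = 0; i < len; ++i) {
          double acc = 0;
          for (int j = -hw; j <= hw; ++j) {
            int ii = i + j;
            if (ii < 0) ii = -ii;                 // reflect
            if (ii >= len) ii = 2 * len - 2 - ii;
            if (ii < 0) ii = 0;
            acc += k[j + hw] * a[base + (size_t)ii * stride];
          }
          b[base + (size_t)i * stride] = acc;
        }
      }
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// 26-connected components of a logical mask; labels 1..k, 0 background.
// [[Rcpp::export]]
IntegerVector cpp_label3(LogicalVector mask, IntegerVector dim) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  size_t ntot = (size_t)d1 * d2 * d3;
  IntegerVector lab(ntot, 0);
  std::vector<size_t> stack;
  int next_lab = 0;
  for (size_t start = 0; start < ntot; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++next_lab;
    lab[start] = next_lab;
    stack.push_back(start);
    while (!stack.empty()) {
      size_t v = stack.back(); stack.pop_back();
      int i1 = (int)(v % d1);
      int i2 = (int)((v / d1) % d2);
      int i3 = (int)(v / ((size_t)d1 * d2));
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          for (int c = -1; c <= 1; ++c) {
            if (a == 0 && b == 0 && c == 0) continue;
            int j1 = i1 + a, j2 = i2 + b, j3 = i3 + c;
            if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3)
              continue;
            size_t w = (size_t)j3 * d1 * d2 + (size_t)j2 * d1 + j1;
            if (mask[w] && lab[w] == 0) { lab[w] = next_lab; stack.push_back(w); }
          }
    }
  }
  return lab;
}

namespace {
// 1D squared distance transform with sample spacing `h` (lower envelope).
void dt1d(const double* f, double* d, int n, double h) {
  std::vector<int> v(n);
  std::vector<double> zz(n + 1);
  int k = 0;
  v[0] = 0;
  zz[0] = -std::numeric_limits<double>::infinity();
  zz[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + h*h*q*q) - (f[p] + h*h*p*p)) / (2.0*h*h*(q - p));
      if (s <= zz[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zz[k] = s;
    zz[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zz[k + 1] < (double)q) ++k;  // envelope stored in index units
    double dq = h * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}
} // namespace

// Euclidean distance (physical units, per-axis spacing) from every voxel to
// the nearest background (FALSE) voxel. Background voxels get 0. Voxels of a
// mask touching the array border measure distance to in-array background only.
// [[Rcpp::export]]
NumericVector cpp_edt3(LogicalVector fg, IntegerVector dim, NumericVector spacing) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  size_t ntot = (size_t)d1 * d2 * d3;
  const double INF = 1e30;
  std::vector<double> a(ntot);
  for (size_t i = 0; i < ntot; ++i) a[i] = fg[i] ? INF : 0.0;

  std::vector<double> f(std::max(d1, std::max(d2, d3)));
  std::vector<double> d(f.size());

  for (int axis = 0; axis < 3; ++axis) {
    int len = axis == 0 ? d1 : (axis == 1 ? d2 : d3);
    size_t stride = axis == 0 ? 1 : (axis == 1 ? (size_t)d1 : (size_t)d1 * d2);
    double h = spacing[axis];
    int n_other1 = axis == 0 ? d2 : d1;
    int n_other2 = axis == 2 ? d2 : d3;
    size_t so1 = axis == 0 ? (size_t)d1 : 1;
    size_t so2 = axis == 2 ? (size_t)d1 : (size_t)d1 * d2;
    for (int u = 0; u < n_other1; ++u) {
      for (int v = 0; v < n_other2; ++v) {
        size_t base = (size_t)u * so1 + (size_t)v * so2;
        for (int i = 0; i < len; ++i) f[i] = a[base + (size_t)i * stride];
        dt1d(f.data(), d.data(), len, h);
        for (int i = 0; i < len; ++i) a[base + (size_t)i * stride] = d[i];
      }
    }
  }
  NumericVector out(ntot);
  for (size_t i = 0; i < ntot; ++i) out[i] = a[i] >= 1e29 ? R_PosInf : std::sqrt(a[i]);
  return out;
}
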
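#include <Rcpp.h>
#include "edt.h"
using namespace Rcpp;

// Exact Euclidean distance (not squared) from every voxel to the nearest
// foreground (nonzero) voxel of a 2D or 3D array. 'spacing' gives the
// physical step along each array dimension. All-background input returns
// +Inf everywhere; callers guard.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, NumericVector spacing) {
  IntegerVector dims = mask.attr("dim");
  const double INF = std::numeric_limits<double>::infinity();
  if (dims.size() == 2) {
    int nr = dims[0], nc = dims[1];
    std::vector<double> g((size_t)nr * nc);
    for (size_t t = 0; t < g.size(); ++t) g[t] = mask[t] != 0 ? 0.0 : INF;
    hepaseg_edt2d_sq(g, nr, nc, spacing[1], spacing[0]);
    NumericVector out(g.size());
    for (size_t t = 0; t < g.size(); ++t) out[t] = std::sqrt(g[t]);
    out.attr("dim") = dims;
    return out;
  }
  if (dims.size() != 3) stop("cpp_edt: array must be 2D or 3D");
  int nr = dims[0], nc = dims[1], nz = dims[2];
  size_t n = (size_t)nr * nc * nz;
  std::vector<double> g(n);
  for (size_t t = 0; t < n; ++t) g[t] = mask[t] != 0 ? 0.0 : INF;
  int nmax = std::max(nr, std::max(nc, nz));
  std::vector<double> f(nmax), d(nmax);
  // axis 1 (rows), spacing[0]
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < nc; ++j) {
      size_t base = (size_t)nr * (j + (size_t)nc * k);
      for (int i = 0; i < nr; ++i) f[i] = g[base + i];
      hepaseg_dt1d(f, d, nr, spacing[0]);
      for (int i = 0; i < nr; ++i) g[base + i] = d[i];
    }
  // axis 2 (cols), spacing[1]
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nr; ++i) {
      size_t base = i + (size_t)nr * nc * k;
      for (int j = 0; j < nc; ++j) f[j] = g[base + (size_t)nr * j];
      hepaseg_dt1d(f, d, nc, spacing[1]);
      for (int j = 0; j < nc; ++j) g[base + (size_t)nr * j] = d[j];
    }
  // axis 3 (slices), spacing[2]
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      size_t base = i + (size_t)nr * j;
      for (int k = 0; k < nz; ++k) f[k] = g[base + (size_t)nr * nc * k];
      hepaseg_dt1d(f, d, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) g[base + (size_t)nr * nc * k] = d[k];
    }
  NumericVector out(n);
  for (size_t t = 0; t < n; ++t) out[t] = std::sqrt(g[t]);
  out.attr("dim") = dims;
  return out;
}

// Signed distance: negative inside (mask != 0), positive outside.
// [[Rcpp::export]]
NumericVector cpp_signed_edt(IntegerVector mask, NumericVector spacing) {
  IntegerVector dims = mask.attr("dim");
  IntegerVector inv(mask.size());
  bool any_fg = false, any_bg = false;
  for (R_xlen_t t = 0; t < mask.size(); ++t) {
    inv[t] = mask[t] != 0 ? 0 : 1;
    if (mask[t] != 0) any_fg = true; else any_bg = true;
  }
  inv.attr("dim") = dims;
  double big = 0.0;
  for (int d = 0; d < dims.size(); ++d) big += dims[d] * spacing[d];
  NumericVector phi(mask.size());
  if (!any_fg || !any_bg) {
    double fill = any_fg ? -big : big;  // uniform mask: no boundary in grid
    std::fill(phi.begin(), phi.end(), fill);
    phi.attr("dim") = dims;
    return phi;
  }
  // the interface lies halfway between foreground and background pixel
  // centers, so distances are offset by half a pixel
  NumericVector dout = cpp_edt(mask, spacing);
  NumericVector din = cpp_edt(inv, spacing);
  double h = 0.5 * (*std::min_element(spacing.begin(), spacing.end()));
  for (R_xlen_t t = 0; t < mask.size(); ++t)
    phi[t] = mask[t] != 0 ? -(din[t] - h) : (dout[t] - h);
  phi.attr("dim") = dims;
  return phi;
}

// 6-connected component labelling of a 3D binary array.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("cpp_label3d: array must be 3D");
  int nr = dims[0], nc = dims[1], nz = dims[2];
  size_t n = (size_t)nr * nc * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      size_t p = stack.back();
      stack.pop_back();
      int k = p / ((size_t)nr * nc);
      int rem = p - (size_t)k * nr * nc;
      int j = rem / nr, i = rem % nr;
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int q = 0; q < 6; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc || kk < 0 || kk >= nz)
          continue;
        size_t pp = ii + (size_t)nr * (jj + (size_t)nc * kk);
        if (mask[pp] != 0 && lab[pp] == 0) {
          lab[pp] = next;
          stack.push_back(pp);
        }
      }
    }
  }
  return lab;
}

// 2D median filter, odd square kernel, reflected edges.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix x, int k) {
  if (k < 3 || k % 2 == 0) stop("kernel must be odd and >= 3");
  int nr = x.nrow(), nc = x.ncol(), h = k / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf((size_t)k * k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      size_t m = 0;
      for (int b = -h; b <= h; ++b) {
        int jj = j + b;
        if (jj < 0) jj = -jj - 1;
        if (jj >= nc) jj = 2 * nc - jj - 1;
        for (int a = -h; a <= h; ++a) {
          int ii = i + a;
          if (ii < 0) ii = -ii - 1;
          if (ii >= nr) ii = 2 * nr - ii - 1;
          buf[m++] = x(ii, jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
      out(i, j) = buf[m / 2];
    }
  }
  return out;
}
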
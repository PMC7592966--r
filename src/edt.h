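#ifndef HEPASEG_EDT_H
#define HEPASEG_EDT_H

#include <vector>
#include <cmath>
#include <limits>

// 1D squared-distance transform of a sampled function (Felzenszwalb &
// Huttenlocher 2012), with sample spacing h. f holds the input parabola
// heights (may be +Inf for "no feature"), d receives the lower envelope.
inline void hepaseg_dt1d(const std::vector<double>& f, std::vector<double>& d,
                         int n, double h) {
  const double INF = std::numeric_limits<double>::infinity();
  const double h2 = h * h;
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;  // index of the rightmost parabola in the envelope
  for (int q = 0; q < n; ++q) {
    if (std::isinf(f[q])) continue;  // infinite parabolas never contribute
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
      continue;
    }
    double s = 0.0;
    for (;;) {
      int vk = v[k];
      s = ((f[q] + h2 * q * q) - (f[vk] + h2 * vk * vk)) /
          (2.0 * h2 * (q - vk));
      if (s <= z[k]) {
        --k;
        if (k < 0) break;
      } else {
        break;
      }
    }
    if (k < 0) {  // new parabola dominates everywhere
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = INF;
    }
  }
  if (k < 0) {  // no finite parabola on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    double dq = (double)(q - v[kk]);
    d[q] = h2 * dq * dq + f[v[kk]];
  }
}

// Squared EDT of a 2D indicator (dist to nearest 'true' pixel), with
// column-major storage (R layout: idx = i + nr*j).
inline void hepaseg_edt2d_sq(std::vector<double>& g, int nr, int nc,
                             double hx, double hy) {
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int j = 0; j < nc; ++j) {  // along rows (first index), spacing hy
    for (int i = 0; i < nr; ++i) f[i] = g[i + (size_t)nr * j];
    hepaseg_dt1d(f, d, nr, hy);
    for (int i = 0; i < nr; ++i) g[i + (size_t)nr * j] = d[i];
  }
  for (int i = 0; i < nr; ++i) {  // along columns, spacing hx
    for (int j = 0; j < nc; ++j) f[j] = g[i + (size_t)nr * j];
    hepaseg_dt1d(f, d, nc, hx);
    for (int j = 0; j < nc; ++j) g[i + (size_t)nr * j] = d[j];
  }
}

#endif
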
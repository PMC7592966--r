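#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- separable Gaussian smoothing with reflected edges -------------------

static std::vector<double> gauss_kernel(double sigma) {
  int hw = (int)std::ceil(3.0 * sigma);
  if (hw < 1) hw = 1;
  std::vector<double> k(2 * hw + 1);
  double s = 0.0;
  for (int t = -hw; t <= hw; ++t) {
    k[t + hw] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + hw];
  }
  for (auto& v : k) v /= s;
  return k;
}

static inline int refl(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// axis: 0 rows, 1 cols, 2 slices; in-place on vector u with dims nr,nc,nz
static void smooth_axis(std::vector<double>& u, int nr, int nc, int nz,
                        int axis, double sigma) {
  if (sigma < 0.05) return;
  std::vector<double> k = gauss_kernel(sigma);
  int hw = ((int)k.size() - 1) / 2;
  size_t nrc = (size_t)nr * nc;
  std::vector<double> line(std::max(nr, std::max(nc, nz)));
  if (axis == 0) {
    for (int z = 0; z < nz; ++z)
      for (int j = 0; j < nc; ++j) {
        size_t base = (size_t)nr * j + nrc * z;
        for (int i = 0; i < nr; ++i) line[i] = u[base + i];
        for (int i = 0; i < nr; ++i) {
          double s = 0.0;
          for (int t = -hw; t <= hw; ++t) s += k[t + hw] * line[refl(i + t, nr)];
          u[base + i] = s;
        }
      }
  } else if (axis == 1) {
    for (int z = 0; z < nz; ++z)
      for (int i = 0; i < nr; ++i) {
        size_t base = i + nrc * z;
        for (int j = 0; j < nc; ++j) line[j] = u[base + (size_t)nr * j];
        for (int j = 0; j < nc; ++j) {
          double s = 0.0;
          for (int t = -hw; t <= hw; ++t) s += k[t + hw] * line[refl(j + t, nc)];
          u[base + (size_t)nr * j] = s;
        }
      }
  } else {
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        size_t base = i + (size_t)nr * j;
        for (int z = 0; z < nz; ++z) line[z] = u[base + nrc * z];
        for (int z = 0; z < nz; ++z) {
          double s = 0.0;
          for (int t = -hw; t <= hw; ++t) s += k[t + hw] * line[refl(z + t, nz)];
          u[base + nrc * z] = s;
        }
      }
  }
}

static void smooth3(std::vector<double>& u, int nr, int nc, int nz,
                    double sx, double sy, double sz) {
  smooth_axis(u, nr, nc, nz, 0, sy);
  smooth_axis(u, nr, nc, nz, 1, sx);
  smooth_axis(u, nr, nc, nz, 2, sz);
}

// ---- edge-enhancing anisotropic diffusion --------------------------------
//
// u_t = div(D grad u), D = I - (1 - g(|grad u_sigma|^2)) n n^T with
// n = grad u_sigma / |grad u_sigma|; g is Weickert's diffusivity
// g(s) = 1 - exp(-Cm / (s/lambda^2)^m) (g(0) = 1). The tensor field is
// smoothed componentwise at scale rho. Explicit conservative face-flux
// scheme with zero-flux boundaries: the intensity sum is conserved exactly.
// hz is the slice spacing in units of the in-plane pixel size.
// [[Rcpp::export]]
NumericVector cpp_eed(NumericVector vol, double hz, double sigma, double rho,
                      double lambda, double tau, int n_steps, double m,
                      double Cm) {
  IntegerVector dims = vol.attr("dim");
  if (dims.size() != 3) stop("cpp_eed: volume must be 3D");
  int nr = dims[0], nc = dims[1], nz = dims[2];
  size_t nrc = (size_t)nr * nc, n = nrc * nz;
  std::vector<double> u(vol.begin(), vol.end());
  std::vector<double> us(n), gx(n), gy(n), gz(n);
  std::vector<double> D11(n), D22(n), D33(n), D12(n), D13(n), D23(n);
  const double lam2 = lambda * lambda;

  auto idx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nr * j + nrc * k;
  };

  for (int step = 0; step < n_steps; ++step) {
    us = u;
    smooth3(us, nr, nc, nz, sigma, sigma, sigma / hz);
    // central-difference gradient of the regularized image (reflect edges
    // give zero one-sided derivative contributions at the boundary)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          size_t p = idx(i, j, k);
          int ip = refl(i + 1, nr), im = refl(i - 1, nr);
          int jp = refl(j + 1, nc), jm = refl(j - 1, nc);
          int kp = refl(k + 1, nz), km = refl(k - 1, nz);
          gy[p] = 0.5 * (us[idx(ip, j, k)] - us[idx(im, j, k)]);
          gx[p] = 0.5 * (us[idx(i, jp, k)] - us[idx(i, jm, k)]);
          gz[p] = 0.5 * (us[idx(i, j, kp)] - us[idx(i, j, km)]) / hz;
        }
    // diffusion tensor
    for (size_t p = 0; p < n; ++p) {
      double s = gx[p] * gx[p] + gy[p] * gy[p] + gz[p] * gz[p];
      if (s <= 1e-30) {
        D11[p] = D22[p] = D33[p] = 1.0;
        D12[p] = D13[p] = D23[p] = 0.0;
        continue;
      }
      double g = 1.0 - std::exp(-Cm / std::pow(s / lam2, m));
      double w = (1.0 - g) / s;  // (1-g) * outer(n,n), n = grad/|grad|
      D11[p] = 1.0 - w * gx[p] * gx[p];
      D22[p] = 1.0 - w * gy[p] * gy[p];
      D33[p] = 1.0 - w * gz[p] * gz[p];
      D12[p] = -w * gx[p] * gy[p];
      D13[p] = -w * gx[p] * gz[p];
      D23[p] = -w * gy[p] * gz[p];
    }
    if (rho > 0.05) {
      smooth3(D11, nr, nc, nz, rho, rho, rho / hz);
      smooth3(D22, nr, nc, nz, rho, rho, rho / hz);
      smooth3(D33, nr, nc, nz, rho, rho, rho / hz);
      smooth3(D12, nr, nc, nz, rho, rho, rho / hz);
      smooth3(D13, nr, nc, nz, rho, rho, rho / hz);
      smooth3(D23, nr, nc, nz, rho, rho, rho / hz);
    }
    // gradient of u itself (central, for tangential face terms)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          size_t p = idx(i, j, k);
          int ip = refl(i + 1, nr), im = refl(i - 1, nr);
          int jp = refl(j + 1, nc), jm = refl(j - 1, nc);
          int kp = refl(k + 1, nz), km = refl(k - 1, nz);
          gy[p] = 0.5 * (u[idx(ip, j, k)] - u[idx(im, j, k)]);
          gx[p] = 0.5 * (u[idx(i, jp, k)] - u[idx(i, jm, k)]);
          gz[p] = 0.5 * (u[idx(i, j, kp)] - u[idx(i, j, km)]) / hz;
        }
    // face fluxes accumulated into the divergence; each interior face
    // contributes +flux to one cell and -flux to its neighbor
    us.assign(n, 0.0);  // reuse as divergence accumulator
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          size_t p = idx(i, j, k);
          if (j + 1 < nc) {  // x-face between (i,j,k) and (i,j+1,k)
            size_t q = idx(i, j + 1, k);
            double du = u[q] - u[p];
            double f = 0.5 * (D11[p] + D11[q]) * du +
                       0.5 * (D12[p] + D12[q]) * 0.5 * (gy[p] + gy[q]) +
                       0.5 * (D13[p] + D13[q]) * 0.5 * (gz[p] + gz[q]);
            us[p] += f;
            us[q] -= f;
          }
          if (i + 1 < nr) {  // y-face
            size_t q = idx(i + 1, j, k);
            double du = u[q] - u[p];
            double f = 0.5 * (D12[p] + D12[q]) * 0.5 * (gx[p] + gx[q]) +
                       0.5 * (D22[p] + D22[q]) * du +
                       0.5 * (D23[p] + D23[q]) * 0.5 * (gz[p] + gz[q]);
            us[p] += f;
            us[q] -= f;
          }
          if (k + 1 < nz) {  // z-face
            size_t q = idx(i, j, k + 1);
            double du = (u[q] - u[p]) / hz;
            double f = (0.5 * (D13[p] + D13[q]) * 0.5 * (gx[p] + gx[q]) +
                        0.5 * (D23[p] + D23[q]) * 0.5 * (gy[p] + gy[q]) +
                        0.5 * (D33[p] + D33[q]) * du) / hz;
            us[p] += f;
            us[q] -= f;
          }
        }
    for (size_t p = 0; p < n; ++p) u[p] += tau * us[p];
  }
  NumericVector out(u.begin(), u.end());
  out.attr("dim") = dims;
  return out;
}
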
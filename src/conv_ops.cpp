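// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Dense kernels for the 2D U-Net: 3x3 same-padding convolution via
// im2col + GEMM, 2x2 max pooling, and 2x2 stride-2 transposed convolution,
// with the matching backward passes. Arrays use R's column-major layout:
// x is (H, W, Cin, N), conv weights are (3, 3, Cin, Cout), transposed-conv
// weights are (2, 2, Cin, Cout).

static void im2col3(const double* x, int H, int W, int Cin, arma::mat& P) {
  // P: (H*W) x (9*Cin); column (a + 3*b + 9*c) holds x(i+a-1, j+b-1, c)
  P.zeros(H * W, 9 * Cin);
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int b = 0; b < 3; ++b) {
      for (int a = 0; a < 3; ++a) {
        double* col = P.colptr(a + 3 * b + 9 * c);
        int di = a - 1, dj = b - 1;
        for (int j = 0; j < W; ++j) {
          int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          const double* src = xc + (size_t)H * jj;
          double* dst = col + (size_t)H * j;
          for (int i = i0; i < i1; ++i) dst[i] = src[i + di];
        }
      }
    }
  }
}

static void col2im3(const arma::mat& P, int H, int W, int Cin, double* x) {
  std::fill(x, x + (size_t)H * W * Cin, 0.0);
  for (int c = 0; c < Cin; ++c) {
    double* xc = x + (size_t)H * W * c;
    for (int b = 0; b < 3; ++b) {
      for (int a = 0; a < 3; ++a) {
        const double* col = P.colptr(a + 3 * b + 9 * c);
        int di = a - 1, dj = b - 1;
        for (int j = 0; j < W; ++j) {
          int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          double* dst = xc + (size_t)H * jj;
          const double* src = col + (size_t)H * j;
          for (int i = i0; i < i1; ++i) dst[i + di] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3_forward(NumericVector x, NumericVector W,
                                NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = W.attr("dim");
  int H = xd[0], Wd = xd[1], Cin = xd[2], N = xd.size() == 4 ? xd[3] : 1;
  int Cout = wd[3];
  arma::mat Wm(const_cast<double*>(W.begin()), 9 * Cin, Cout, false);
  NumericVector y((size_t)H * Wd * Cout * N);
  y.attr("dim") = IntegerVector::create(H, Wd, Cout, N);
  arma::mat P;
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (size_t)H * Wd * Cin * n, H, Wd, Cin, P);
    arma::mat Y(y.begin() + (size_t)H * Wd * Cout * n, H * Wd, Cout, false,
                true);
    Y = P * Wm;
    Y.each_row() += arma::rowvec(const_cast<double*>(bias.begin()), Cout,
                                 false);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3_backward(NumericVector x, NumericVector W, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = W.attr("dim");
  int H = xd[0], Wd = xd[1], Cin = xd[2], N = xd.size() == 4 ? xd[3] : 1;
  int Cout = wd[3];
  arma::mat Wm(const_cast<double*>(W.begin()), 9 * Cin, Cout, false);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dW(W.size());
  dW.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dWm(dW.begin(), 9 * Cin, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  arma::mat P, dP;
  for (int n = 0; n < N; ++n) {
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)H * Wd * Cout * n,
                 H * Wd, Cout, false);
    im2col3(x.begin() + (size_t)H * Wd * Cin * n, H, Wd, Cin, P);
    dWm += P.t() * dY;
    dbv += arma::sum(dY, 0);
    dP = dY * Wm.t();
    col2im3(dP, H, Wd, Cin, dx.begin() + (size_t)H * Wd * Cin * n);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd.size() == 4 ? xd[3] : 1;
  int h = H / 2, w = W / 2;
  NumericVector y((size_t)h * w * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(h, w, C, N);
  idx.attr("dim") = IntegerVector::create(h, w, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < w; ++j)
        for (int i = 0; i < h; ++i) {
          int best = 0;
          double bv = xc[(size_t)(2 * i) + (size_t)H * (2 * j)];
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a) {
              double v = xc[(size_t)(2 * i + a) + (size_t)H * (2 * j + b)];
              if (v > bv) {
                bv = v;
                best = a + 2 * b;
              }
            }
          size_t q = (size_t)i + (size_t)h * j +
                     (size_t)h * w * (c + (size_t)C * n);
          y[q] = bv;
          idx[q] = best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dy, IntegerVector idx,
                                    int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int h = yd[0], w = yd[1], C = yd[2], N = yd.size() == 4 ? yd[3] : 1;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < w; ++j)
        for (int i = 0; i < h; ++i) {
          size_t q = (size_t)i + (size_t)h * j +
                     (size_t)h * w * (c + (size_t)C * n);
          int a = idx[q] % 2, b = idx[q] / 2;
          xc[(size_t)(2 * i + a) + (size_t)H * (2 * j + b)] += dy[q];
        }
    }
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upconv2_forward(NumericVector x, NumericVector W,
                                  NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = W.attr("dim");
  int H = xd[0], Wd = xd[1], Cin = xd[2], N = xd.size() == 4 ? xd[3] : 1;
  int Cout = wd[3];
  int H2 = 2 * H, W2 = 2 * Wd;
  NumericVector y((size_t)H2 * W2 * Cout * N);
  y.attr("dim") = IntegerVector::create(H2, W2, Cout, N);
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o) {
      double* yo = y.begin() + (size_t)H2 * W2 * (o + (size_t)Cout * n);
      for (size_t t = 0; t < (size_t)H2 * W2; ++t) yo[t] = bias[o];
      for (int c = 0; c < Cin; ++c) {
        const double* xc = x.begin() + (size_t)H * Wd * (c + (size_t)Cin * n);
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a) {
            double wv = W[(size_t)a + 2 * b + 4 * c + (size_t)4 * Cin * o];
            for (int j = 0; j < Wd; ++j) {
              double* dst = yo + (size_t)H2 * (2 * j + b) + a;
              const double* src = xc + (size_t)H * j;
              for (int i = 0; i < H; ++i) dst[2 * i] += wv * src[i];
            }
          }
      }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_upconv2_backward(NumericVector x, NumericVector W, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = W.attr("dim");
  int H = xd[0], Wd = xd[1], Cin = xd[2], N = xd.size() == 4 ? xd[3] : 1;
  int Cout = wd[3];
  int H2 = 2 * H, W2 = 2 * Wd;
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dW(W.size());
  dW.attr("dim") = wd;
  NumericVector db(Cout);
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o) {
      const double* go = dy.begin() + (size_t)H2 * W2 * (o + (size_t)Cout * n);
      double s = 0.0;
      for (size_t t = 0; t < (size_t)H2 * W2; ++t) s += go[t];
      db[o] += s;
      for (int c = 0; c < Cin; ++c) {
        const double* xc = x.begin() + (size_t)H * Wd * (c + (size_t)Cin * n);
        double* dxc = dx.begin() + (size_t)H * Wd * (c + (size_t)Cin * n);
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a) {
            size_t widx = (size_t)a + 2 * b + 4 * c + (size_t)4 * Cin * o;
            double wv = W[widx], dwv = 0.0;
            for (int j = 0; j < Wd; ++j) {
              const double* gsrc = go + (size_t)H2 * (2 * j + b) + a;
              const double* src = xc + (size_t)H * j;
              double* ddst = dxc + (size_t)H * j;
              for (int i = 0; i < H; ++i) {
                double g = gsrc[2 * i];
                dwv += g * src[i];
                ddst[i] += wv * g;
              }
            }
            dW[widx] += dwv;
          }
      }
    }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
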
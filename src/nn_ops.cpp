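// Minimal conv-net kernels: batched 2-D convolution forward/backward via im2col.
// Tensors are R arrays in (H, W, C, N) layout; weights are (kh, kw, Cin, Cout).
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Gather one sample's receptive fields into a (kh*kw*Cin) x (Ho*Wo) matrix.
// Column entry order: ki fastest, then kj, then c — matching the R flattening
// of a (kh, kw, Cin, Cout) weight array.
static void im2col(const double* x, int H, int W, int Cin,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int p = ho + Ho * wo;
      double* dst = col.colptr(p);
      for (int c = 0; c < Cin; ++c) {
        const double* xc = x + (size_t)H * W * c;
        for (int kj = 0; kj < kw; ++kj) {
          int wi = wo * stride + kj - pad;
          bool wok = (wi >= 0 && wi < W);
          for (int ki = 0; ki < kh; ++ki) {
            int hi = ho * stride + ki - pad;
            double v = 0.0;
            if (wok && hi >= 0 && hi < H) v = xc[hi + (size_t)H * wi];
            dst[ki + kh * (kj + kw * c)] = v;
          }
        }
      }
    }
  }
}

// Scatter-add of a column matrix back onto the input grid (adjoint of im2col).
static void col2im(const arma::mat& col, int H, int W, int Cin,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* gx) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int p = ho + Ho * wo;
      const double* src = col.colptr(p);
      for (int c = 0; c < Cin; ++c) {
        double* gc = gx + (size_t)H * W * c;
        for (int kj = 0; kj < kw; ++kj) {
          int wi = wo * stride + kj - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            int hi = ho * stride + ki - pad;
            if (hi < 0 || hi >= H) continue;
            gc[hi + (size_t)H * wi] += src[ki + kh * (kj + kw * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".nn_conv_fwd")]]
NumericVector nn_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                          int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("weight Cin mismatch");
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("kernel larger than padded input");

  arma::mat wmat(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout, false);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col((size_t)kh * kw * Cin, (size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * Cin * n;
    im2col(xn, H, W, Cin, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat ycol = wmat.t() * col;       // Cout x (Ho*Wo)
    double* yn = y.begin() + (size_t)Ho * Wo * Cout * n;
    for (int c = 0; c < Cout; ++c) {
      double bc = b[c];
      double* yc = yn + (size_t)Ho * Wo * c;
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) yc[p] = ycol(c, p) + bc;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".nn_conv_bwd")]]
List nn_conv_bwd(NumericVector x, NumericVector w, NumericVector gy,
                 int stride, int pad, bool need_gx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];

  arma::mat wmat(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout, false);
  arma::mat gw((size_t)kh * kw * Cin, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  NumericVector gx;
  if (need_gx) {
    gx = NumericVector((size_t)H * W * Cin * N);
    gx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  }
  arma::mat col((size_t)kh * kw * Cin, (size_t)Ho * Wo);
  arma::mat gycol(Cout, (size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * Cin * n;
    const double* gn = gy.begin() + (size_t)Ho * Wo * Cout * n;
    for (int c = 0; c < Cout; ++c)
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
        gycol(c, p) = gn[p + (size_t)Ho * Wo * c];
    im2col(xn, H, W, Cin, kh, kw, stride, pad, Ho, Wo, col);
    gw += col * gycol.t();
    gb += arma::sum(gycol, 1);
    if (need_gx) {
      arma::mat gcol = wmat * gycol;
      double* gxn = gx.begin() + (size_t)H * W * Cin * n;
      col2im(gcol, H, W, Cin, kh, kw, stride, pad, Ho, Wo, gxn);
    }
  }
  NumericVector gwv(gw.begin(), gw.end());
  gwv.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  return List::create(_["gx"] = need_gx ? (SEXP)gx : R_NilValue,
                      _["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}
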
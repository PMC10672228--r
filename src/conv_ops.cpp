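// 2D convolution primitives used by the translation networks.
// Tensor layout follows R's column-major arrays:
//   activations: (H, W, C, N)   weights: (KH, KW, Cin, Cout)
// All three primitives (forward, data-gradient, filter-gradient) are exposed
// so that transposed convolution is expressed in R as the adjoint of a
// forward convolution, with no separate kernel needed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

static void get_dims4(const NumericVector& x, int* d) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// col(r, ho + Ho*wo) with r = kh + KH*(kw + KW*c); zero padding.
static void im2col(const double* x, int H, int W, int C, long n,
                   int KH, int KW, int s, int p, int Ho, int Wo,
                   arma::mat& col) {
  const long strideC = (long)H * W;
  const long base = strideC * C * n;
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + base + strideC * c;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        const int r = kh + KH * (kw + KW * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - p + kw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * s - p + kh;
            if (hi < 0 || hi >= H) continue;
            col(r, ho + (long)Ho * wo) = xc[hi + (long)H * wi];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, double* gx, int H, int W, int C,
                       long n, int KH, int KW, int s, int p, int Ho, int Wo) {
  const long strideC = (long)H * W;
  const long base = strideC * C * n;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + base + strideC * c;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        const int r = kh + KH * (kw + KW * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - p + kw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * s - p + kh;
            if (hi < 0 || hi >= H) continue;
            gc[hi + (long)H * wi] += col(r, ho + (long)Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  int xd[4], wd[4];
  get_dims4(x, xd);
  get_dims4(w, wd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch: input has %d, kernel expects %d", C, Cin);
  const int Ho = out_dim(H, KH, stride, pad), Wo = out_dim(W, KW, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("non-positive output size");

  arma::mat Wm(const_cast<double*>(w.begin()), (long)KH * KW * Cin, Cout, false, true);
  NumericVector out((long)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double* op = out.begin();
  arma::mat col((long)KH * KW * Cin, (long)Ho * Wo);
  for (long n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, C, n, KH, KW, stride, pad, Ho, Wo, col);
    arma::mat om = Wm.t() * col;  // (Cout, Ho*Wo)
    const long basen = (long)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const double bc = b[co];
      double* oc = op + basen + (long)Ho * Wo * co;
      for (long q = 0; q < (long)Ho * Wo; ++q) oc[q] = om(co, q) + bc;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gout,
                         int stride, int pad, bool need_gx, bool need_gw) {
  int xd[4], wd[4], gd[4];
  get_dims4(x, xd);
  get_dims4(w, wd);
  get_dims4(gout, gd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  if (gd[2] != Cout || gd[3] != N) stop("gradient dims inconsistent with weights/input");

  arma::mat Wm(const_cast<double*>(w.begin()), (long)KH * KW * Cin, Cout, false, true);
  NumericVector gx(need_gx ? (long)H * W * C * N : 1);
  if (need_gx) gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector gw((long)KH * KW * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(KH, KW, Cin, Cout);
  NumericVector gb(Cout);
  arma::mat gWm(gw.begin(), (long)KH * KW * Cin, Cout, false, true);

  arma::mat col((long)KH * KW * Cin, (long)Ho * Wo);
  arma::mat gm(Cout, (long)Ho * Wo);
  const double* gp = gout.begin();
  for (long n = 0; n < N; ++n) {
    const long basen = (long)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const double* gc = gp + basen + (long)Ho * Wo * co;
      double acc = 0.0;
      for (long q = 0; q < (long)Ho * Wo; ++q) { gm(co, q) = gc[q]; acc += gc[q]; }
      gb[co] += acc;
    }
    if (need_gw) {
      im2col(x.begin(), H, W, C, n, KH, KW, stride, pad, Ho, Wo, col);
      gWm += col * gm.t();
    }
    if (need_gx) {
      arma::mat gcol = Wm * gm;
      col2im_add(gcol, gx.begin(), H, W, C, n, KH, KW, stride, pad, Ho, Wo);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Data gradient alone: the forward pass of a transposed convolution.
// gout: (Ho, Wo, Cout, N) in the *convolution* view; returns (H, W, Cin, N).
// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_data(NumericVector gout, NumericVector w,
                                  int stride, int pad, int H, int W) {
  int wd[4], gd[4];
  get_dims4(w, wd);
  get_dims4(gout, gd);
  const int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1], N = gd[3];
  if (gd[2] != Cout) stop("channel mismatch in transposed convolution");
  if (out_dim(H, KH, stride, pad) != Ho || out_dim(W, KW, stride, pad) != Wo)
    stop("target size (%d, %d) is not reachable from (%d, %d) with this kernel",
         H, W, Ho, Wo);

  arma::mat Wm(const_cast<double*>(w.begin()), (long)KH * KW * Cin, Cout, false, true);
  NumericVector gx((long)H * W * Cin * N);
  gx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  arma::mat gm(Cout, (long)Ho * Wo);
  const double* gp = gout.begin();
  for (long n = 0; n < N; ++n) {
    const long basen = (long)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const double* gc = gp + basen + (long)Ho * Wo * co;
      for (long q = 0; q < (long)Ho * Wo; ++q) gm(co, q) = gc[q];
    }
    arma::mat gcol = Wm * gm;
    col2im_add(gcol, gx.begin(), H, W, Cin, n, KH, KW, stride, pad, Ho, Wo);
  }
  return gx;
}
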
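// Convolution and pooling kernels for the CNN engine.
// Layout convention: activations are (H, W, C, N) double arrays, weights are
// (KH, KW, Cin, Cout). im2col builds the transposed patch matrix (P x K) with
// P = Ho*Wo and K = KH*KW*Cin so that both the gemm output and the R weight
// array are used in their natural column-major order. Patch matrices and gemm
// run in single precision: the buffers dominate memory traffic and sgemm is
// twice as fast as dgemm, while parameters and gradients stay double on the R
// side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill colT (P x K) from image slice xn (H x W x C doubles).
static void im2col_t(const double* xn, int H, int W, int C,
                     int KH, int KW, int stride, int pad,
                     int Ho, int Wo, arma::fmat& colT) {
  const int P = Ho * Wo;
  if (pad > 0) colT.zeros();
  float* out = colT.memptr();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        const int k = kh + KH * (kw + KW * c);
        float* col = out + (size_t)k * P;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          const double* src = xn + (size_t)c * H * W + (size_t)w * H;
          float* dst = col + (size_t)wo * Ho;
          const int h0 = std::max(0, (pad - kh + stride - 1) / stride);
          const int h1 = std::min(Ho, (H - 1 - kh + pad) / stride + 1);
          for (int ho = h0; ho < h1; ++ho) {
            dst[ho] = (float)src[ho * stride - pad + kh];
          }
        }
      }
    }
  }
}

// Scatter-add gColT (P x K) into the double gradient slice gxn.
static void col2im_t(const arma::fmat& gColT, double* gxn, int H, int W, int C,
                     int KH, int KW, int stride, int pad, int Ho, int Wo) {
  const int P = Ho * Wo;
  const float* in = gColT.memptr();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        const int k = kh + KH * (kw + KW * c);
        const float* col = in + (size_t)k * P;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          double* dst = gxn + (size_t)c * H * W + (size_t)w * H;
          const float* src = col + (size_t)wo * Ho;
          const int h0 = std::max(0, (pad - kh + stride - 1) / stride);
          const int h1 = std::min(Ho, (H - 1 - kh + pad) / stride + 1);
          for (int ho = h0; ho < h1; ++ho) {
            dst[ho * stride - pad + kh] += src[ho];
          }
        }
      }
    }
  }
}

static arma::fmat to_fmat(const double* p, int nr, int nc) {
  arma::fmat out(nr, nc);
  float* o = out.memptr();
  const size_t n = (size_t)nr * nc;
  for (size_t i = 0; i < n; ++i) o[i] = (float)p[i];
  return out;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  const int Ho = out_size(H, KH, stride, pad), Wo = out_size(W, KW, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  const int P = Ho * Wo, K = KH * KW * C;

  NumericVector y((size_t)P * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::fmat Wflat = to_fmat(w.begin(), K, Cout);
  arma::fmat colT(P, K), Yn(P, Cout);
  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin() + (size_t)n * H * W * C, H, W, C, KH, KW, stride, pad,
             Ho, Wo, colT);
    Yn = colT * Wflat;
    double* yp = y.begin() + (size_t)n * P * Cout;
    const float* yn = Yn.memptr();
    for (int co = 0; co < Cout; ++co) {
      const double bias = b[co];
      for (int p = 0; p < P; ++p) yp[(size_t)co * P + p] = yn[(size_t)co * P + p] + bias;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], Cout = wd[3];
  const int Ho = out_size(H, KH, stride, pad), Wo = out_size(W, KW, stride, pad);
  const int P = Ho * Wo, K = KH * KW * C;

  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Cout);

  arma::fmat Wflat = to_fmat(w.begin(), K, Cout);
  arma::fmat colT(P, K), gColT(P, K), gYn(P, Cout), gWn(K, Cout);
  for (int n = 0; n < N; ++n) {
    const double* gyp = gy.begin() + (size_t)n * P * Cout;
    float* gf = gYn.memptr();
    for (size_t i = 0; i < (size_t)P * Cout; ++i) gf[i] = (float)gyp[i];
    im2col_t(x.begin() + (size_t)n * H * W * C, H, W, C, KH, KW, stride, pad,
             Ho, Wo, colT);
    gWn = colT.t() * gYn;
    {
      const float* s = gWn.memptr();
      double* d = gw.begin();
      for (size_t i = 0; i < (size_t)K * Cout; ++i) d[i] += s[i];
    }
    for (int co = 0; co < Cout; ++co) {
      double acc = 0;
      for (int p = 0; p < P; ++p) acc += gyp[(size_t)co * P + p];
      gb[co] += acc;
    }
    gColT = gYn * Wflat.t();
    col2im_t(gColT, gx.begin() + (size_t)n * H * W * C, H, W, C, KH, KW,
             stride, pad, Ho, Wo);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("maxpool: output size would be empty");

  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());  // 1-based linear index into x of each max
  idx.attr("dim") = y.attr("dim");

  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    const size_t base = (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      const size_t cb = base + (size_t)c * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho, ++o) {
          double best = R_NegInf;
          size_t best_i = 0;
          for (int kw = 0; kw < k; ++kw) {
            const int w = wo * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h = ho * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              const size_t i = cb + (size_t)w * H + h;
              if (xp[i] > best) { best = xp[i]; best_i = i; }
            }
          }
          yp[o] = best;
          ip[o] = (int)(best_i + 1);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  size_t total = 1;
  for (int i = 0; i < xdim.size(); ++i) total *= (size_t)xdim[i];
  NumericVector gx(total);
  gx.attr("dim") = xdim;
  double* gp = gx.begin();
  for (R_xlen_t o = 0; o < gy.size(); ++o) gp[idx[o] - 1] += gy[o];
  return gx;
}

// ---- fused elementwise helpers (single-pass versions of hot R idioms) ----

// y[i] = x[i] * scale[c] + shift[c], c = channel of element i.
// [[Rcpp::export(name = ".scale_shift")]]
NumericVector scale_shift(NumericVector x, NumericVector scale,
                          NumericVector shift, int hw) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const int C = scale.size();
  const size_t n = x.size(), block = (size_t)hw;
  const double *xp = x.begin();
  double *yp = y.begin();
  size_t i = 0;
  while (i < n) {
    for (int c = 0; c < C && i < n; ++c) {
      const double s = scale[c], t = shift[c];
      const size_t end = i + block;
      for (; i < end; ++i) yp[i] = xp[i] * s + t;
    }
  }
  return y;
}

// Per-channel sums and sums of squares over (hw, C, N)-shaped data.
// [[Rcpp::export(name = ".channel_stats")]]
List channel_stats(NumericVector x, int hw, int C) {
  NumericVector s(C), s2(C);
  const double *xp = x.begin();
  const size_t n = x.size(), block = (size_t)hw;
  size_t i = 0;
  while (i < n) {
    for (int c = 0; c < C && i < n; ++c) {
      double a = 0, a2 = 0;
      const size_t end = i + block;
      for (; i < end; ++i) { a += xp[i]; a2 += xp[i] * xp[i]; }
      s[c] += a; s2[c] += a2;
    }
  }
  return List::create(_["sum"] = s, _["sumsq"] = s2);
}

// Per-channel sums of g and of g*xhat (batch-norm backward reductions).
// [[Rcpp::export(name = ".channel_dot")]]
List channel_dot(NumericVector g, NumericVector xhat, int hw, int C) {
  NumericVector s(C), d(C);
  const double *gp = g.begin(), *xp = xhat.begin();
  const size_t n = g.size(), block = (size_t)hw;
  size_t i = 0;
  while (i < n) {
    for (int c = 0; c < C && i < n; ++c) {
      double a = 0, b = 0;
      const size_t end = i + block;
      for (; i < end; ++i) { a += gp[i]; b += gp[i] * xp[i]; }
      s[c] += a; d[c] += b;
    }
  }
  return List::create(_["sum"] = s, _["dot"] = d);
}

// gx[i] = (g[i]*gamma[c] - a[c] - xhat[i]*b[c]) * inv_std[c]
// [[Rcpp::export(name = ".bn_bwd_fused")]]
NumericVector bn_bwd_fused(NumericVector g, NumericVector xhat,
                           NumericVector gamma, NumericVector a,
                           NumericVector b, NumericVector inv_std, int hw) {
  NumericVector gx(g.size());
  gx.attr("dim") = g.attr("dim");
  const int C = gamma.size();
  const double *gp = g.begin(), *xp = xhat.begin();
  double *op = gx.begin();
  const size_t n = g.size(), block = (size_t)hw;
  size_t i = 0;
  while (i < n) {
    for (int c = 0; c < C && i < n; ++c) {
      const double ga = gamma[c], ac = a[c], bc = b[c], is = inv_std[c];
      const size_t end = i + block;
      for (; i < end; ++i) op[i] = (gp[i] * ga - ac - xp[i] * bc) * is;
    }
  }
  return gx;
}

// [[Rcpp::export(name = ".relu_fwd")]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double *xp = x.begin();
  double *yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return y;
}

// gx = g where y > 0 else 0 (y is the ReLU output).
// [[Rcpp::export(name = ".relu_bwd")]]
NumericVector relu_bwd(NumericVector g, NumericVector y) {
  NumericVector gx(g.size());
  gx.attr("dim") = g.attr("dim");
  const double *gp = g.begin(), *yp = y.begin();
  double *op = gx.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i) op[i] = yp[i] > 0 ? gp[i] : 0;
  return gx;
}

// relu(a + b), the residual-block merge.
// [[Rcpp::export(name = ".add_relu")]]
NumericVector add_relu(NumericVector a, NumericVector b) {
  NumericVector y(a.size());
  y.attr("dim") = a.attr("dim");
  const double *ap = a.begin(), *bp = b.begin();
  double *yp = y.begin();
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    const double v = ap[i] + bp[i];
    yp[i] = v > 0 ? v : 0;
  }
  return y;
}
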
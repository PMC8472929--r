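// Minimal CPU kernels for the convolutional network: im2col-based 2-D
// convolution (forward + backward) and max/average pooling. Tensors are R
// arrays in column-major layout with dim = (H, W, C, N); convolution weights
// have dim = (kh, kw, in_channels, out_channels).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_side(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill `cols` (kh*kw*Cin x Ho*Wo) from one sample's data.
// Column j = ho + Ho*wo; row r = i + kh*(j_ + kw*c).
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& cols) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int col = ho + Ho * wo;
      double* dst = cols.colptr(col);
      int h0 = ho * stride - pad;
      int w0 = wo * stride - pad;
      int r = 0;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)H * W * c;
        for (int j = 0; j < kw; ++j) {
          int wi = w0 + j;
          for (int i = 0; i < kh; ++i, ++r) {
            int hi = h0 + i;
            dst[r] = (hi >= 0 && hi < H && wi >= 0 && wi < W)
                       ? xc[hi + (size_t)H * wi] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add of `cols` back into one sample's gradient image.
static void col2im(const arma::mat& cols, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* dx) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      int col = ho + Ho * wo;
      const double* src = cols.colptr(col);
      int h0 = ho * stride - pad;
      int w0 = wo * stride - pad;
      int r = 0;
      for (int c = 0; c < C; ++c) {
        double* xc = dx + (size_t)H * W * c;
        for (int j = 0; j < kw; ++j) {
          int wi = w0 + j;
          for (int i = 0; i < kh; ++i, ++r) {
            int hi = h0 + i;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              xc[hi + (size_t)H * wi] += src[r];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  if (Ci != C) stop("conv2d: input has %d channels, weight expects %d", C, Ci);
  int Ho = out_side(H, kh, stride, pad), Wo = out_side(W, kw, stride, pad);
  int K = kh * kw * C, P = Ho * Wo;

  arma::mat Wm(const_cast<double*>(w.begin()), K, Co, false, true);
  NumericVector out((size_t)P * Co * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  arma::mat cols(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C,
           kh, kw, stride, pad, Ho, Wo, cols);
    arma::mat on(out.begin() + (size_t)P * Co * n, P, Co, false, true);
    on = cols.t() * Wm;
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dout,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Co = wd[3];
  int Ho = out_side(H, kh, stride, pad), Wo = out_side(W, kw, stride, pad);
  int K = kh * kw * C, P = Ho * Wo;

  arma::mat Wm(const_cast<double*>(w.begin()), K, Co, false, true);
  NumericVector dx((size_t)H * W * C * N), dw((size_t)K * Co);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  arma::mat dWm(dw.begin(), K, Co, false, true);
  arma::mat cols(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C,
           kh, kw, stride, pad, Ho, Wo, cols);
    arma::mat dn(const_cast<double*>(dout.begin()) + (size_t)P * Co * n,
                 P, Co, false, true);
    dWm += cols * dn;
    arma::mat dcols = Wm * dn.t();
    col2im(dcols, H, W, C, kh, kw, stride, pad, Ho, Wo,
           dx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export]]
List maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_side(H, k, stride, pad), Wo = out_side(W, k, stride, pad);
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector amax((size_t)Ho * Wo * C * N);  // 0-based linear index into x

  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          int h0 = ho * stride - pad, w0 = wo * stride - pad;
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int j = 0; j < k; ++j) {
            int wi = w0 + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = h0 + i;
              if (hi < 0 || hi >= H) continue;
              double v = xc[hi + (size_t)H * wi];
              if (v > best) { best = v; bidx = base + hi + (size_t)H * wi; }
            }
          }
          // column-major output: index ho + Ho*(wo + Wo*(c + C*n))
          size_t oi = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * (c + (size_t)C * n));
          out[oi] = best;
          amax[oi] = (int)bidx;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(NumericVector dout, IntegerVector argmax,
                          IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[argmax[i]] += dout[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector avgpool_fwd(NumericVector x, int k, int stride) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_side(H, k, stride, 0), Wo = out_side(W, k, stride, 0);
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double s = 0;
          for (int j = 0; j < k; ++j)
            for (int i = 0; i < k; ++i)
              s += xc[(ho * stride + i) + (size_t)H * (wo * stride + j)];
          out[(size_t)ho + (size_t)Ho * (wo + (size_t)Wo * (c + (size_t)C * n))] = s * inv;
        }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector avgpool_bwd(NumericVector dout, IntegerVector xdim,
                          int k, int stride) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = out_side(H, k, stride, 0), Wo = out_side(W, k, stride, 0);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double g = dout[(size_t)ho + (size_t)Ho * (wo + (size_t)Wo * (c + (size_t)C * n))] * inv;
          for (int j = 0; j < k; ++j)
            for (int i = 0; i < k; ++i)
              xc[(ho * stride + i) + (size_t)H * (wo * stride + j)] += g;
        }
    }
  return dx;
}
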
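// Low-level numeric kernels for the segmentation network.
//
// Tensor layout throughout: column-major R arrays with dim (N, C, H, W),
// i.e. element (n, c, h, w) lives at n + N*(c + C*(h + H*w)).
// Convolution weights: dim (CO, CI, KH, KW).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Gather one sample into an im2col matrix: rows ci + CI*(kh + KH*kw),
// columns oh + OH*ow. Zero padding.
static void im2col(const double* x, int n, int N, int CI, int H, int W,
                   int KH, int KW, int stride, int pad,
                   int OH, int OW, arma::mat& col) {
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      const int c_idx = oh + OH * ow;
      for (int kw = 0; kw < KW; ++kw) {
        const int w_in = ow * stride - pad + kw;
        for (int kh = 0; kh < KH; ++kh) {
          const int h_in = oh * stride - pad + kh;
          double* dst = col.colptr(c_idx) + CI * (kh + KH * kw);
          if (h_in < 0 || h_in >= H || w_in < 0 || w_in >= W) {
            for (int ci = 0; ci < CI; ++ci) dst[ci] = 0.0;
          } else {
            const double* src = x + n + (size_t)N * (0 + (size_t)CI * (h_in + (size_t)H * w_in));
            for (int ci = 0; ci < CI; ++ci) dst[ci] = src[(size_t)N * ci];
          }
        }
      }
    }
  }
}

// Scatter-add the transpose operation of im2col.
static void col2im(const arma::mat& col, double* gx, int n, int N, int CI,
                   int H, int W, int KH, int KW, int stride, int pad,
                   int OH, int OW) {
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      const int c_idx = oh + OH * ow;
      for (int kw = 0; kw < KW; ++kw) {
        const int w_in = ow * stride - pad + kw;
        if (w_in < 0 || w_in >= W) continue;
        for (int kh = 0; kh < KH; ++kh) {
          const int h_in = oh * stride - pad + kh;
          if (h_in < 0 || h_in >= H) continue;
          const double* src = col.colptr(c_idx) + CI * (kh + KH * kw);
          double* dst = gx + n + (size_t)N * (0 + (size_t)CI * (h_in + (size_t)H * w_in));
          for (int ci = 0; ci < CI; ++ci) dst[(size_t)N * ci] += src[ci];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], CI = xd[1], H = xd[2], W = xd[3];
  const int CO = wd[0], KH = wd[2], KW = wd[3];
  if (wd[1] != CI) stop("conv2d: weight expects %d input channels, got %d", wd[1], CI);
  const int OH = out_size(H, KH, stride, pad), OW = out_size(W, KW, stride, pad);
  if (OH < 1 || OW < 1) stop("conv2d: output would be empty (input %dx%d, kernel %d)", H, W, KH);

  NumericVector y((size_t)N * CO * OH * OW);
  y.attr("dim") = IntegerVector::create(N, CO, OH, OW);
  arma::mat Wm(const_cast<double*>(w.begin()), CO, (size_t)CI * KH * KW, false, true);
  arma::mat col((size_t)CI * KH * KW, (size_t)OH * OW);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), n, N, CI, H, W, KH, KW, stride, pad, OH, OW, col);
    arma::mat out = Wm * col;  // CO x OH*OW
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        const double* src = out.colptr(oh + OH * ow);
        double* dst = y.begin() + n + (size_t)N * (0 + (size_t)CO * (oh + (size_t)OH * ow));
        for (int co = 0; co < CO; ++co) dst[(size_t)N * co] = src[co] + b[co];
      }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], CI = xd[1], H = xd[2], W = xd[3];
  const int CO = wd[0], KH = wd[2], KW = wd[3];
  const int OH = out_size(H, KH, stride, pad), OW = out_size(W, KW, stride, pad);

  NumericVector gx((size_t)N * CI * H * W);
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(CO);

  arma::mat Wm(const_cast<double*>(w.begin()), CO, (size_t)CI * KH * KW, false, true);
  arma::mat Gw(gw.begin(), CO, (size_t)CI * KH * KW, false, true);
  arma::mat col((size_t)CI * KH * KW, (size_t)OH * OW);
  arma::mat gyn(CO, (size_t)OH * OW);

  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        const double* src = gy.begin() + n + (size_t)N * (0 + (size_t)CO * (oh + (size_t)OH * ow));
        double* dst = gyn.colptr(oh + OH * ow);
        for (int co = 0; co < CO; ++co) dst[co] = src[(size_t)N * co];
      }
    im2col(x.begin(), n, N, CI, H, W, KH, KW, stride, pad, OH, OW, col);
    Gw += gyn * col.t();
    for (int co = 0; co < CO; ++co) gb[co] += arma::accu(gyn.row(co));
    arma::mat gcol = Wm.t() * gyn;
    col2im(gcol, gx.begin(), n, N, CI, H, W, KH, KW, stride, pad, OH, OW);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int OH = out_size(H, k, stride, pad), OW = out_size(W, k, stride, pad);

  NumericVector y((size_t)N * C * OH * OW);
  y.attr("dim") = IntegerVector::create(N, C, OH, OW);
  IntegerVector arg(y.size());  // 0-based linear index into x

  for (int ow = 0; ow < OW; ++ow)
    for (int oh = 0; oh < OH; ++oh)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double best = -INFINITY;
          long long best_idx = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int w_in = ow * stride - pad + kw;
            if (w_in < 0 || w_in >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h_in = oh * stride - pad + kh;
              if (h_in < 0 || h_in >= H) continue;
              const long long idx = n + (long long)N * (c + (long long)C * (h_in + (long long)H * w_in));
              if (x[idx] > best) { best = x[idx]; best_idx = idx; }
            }
          }
          const long long out_idx = n + (long long)N * (c + (long long)C * (oh + (long long)OH * ow));
          y[out_idx] = best;
          arg[out_idx] = (int)best_idx;
        }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector gy, IntegerVector argmax,
                                   IntegerVector x_dim) {
  size_t n_in = (size_t)x_dim[0] * x_dim[1] * x_dim[2] * x_dim[3];
  NumericVector gx(n_in);
  gx.attr("dim") = x_dim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[argmax[i]] += gy[i];
  return gx;
}

// Bilinear interpolation with the half-pixel (align_corners = FALSE) convention.
static inline void src_coord(int i, int in, int out, int& i0, int& i1, double& f) {
  double s = (i + 0.5) * ((double)in / out) - 0.5;
  if (s < 0) s = 0;
  if (s > in - 1) s = in - 1;
  i0 = (int)std::floor(s);
  i1 = i0 + 1 < in ? i0 + 1 : in - 1;
  f = s - i0;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_forward(NumericVector x, int out_h, int out_w) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  NumericVector y((size_t)N * C * out_h * out_w);
  y.attr("dim") = IntegerVector::create(N, C, out_h, out_w);
  const size_t NC = (size_t)N * C;

  for (int ow = 0; ow < out_w; ++ow) {
    int w0, w1; double fw;
    src_coord(ow, W, out_w, w0, w1, fw);
    for (int oh = 0; oh < out_h; ++oh) {
      int h0, h1; double fh;
      src_coord(oh, H, out_h, h0, h1, fh);
      const double* p00 = x.begin() + NC * (h0 + (size_t)H * w0);
      const double* p10 = x.begin() + NC * (h1 + (size_t)H * w0);
      const double* p01 = x.begin() + NC * (h0 + (size_t)H * w1);
      const double* p11 = x.begin() + NC * (h1 + (size_t)H * w1);
      double* dst = y.begin() + NC * (oh + (size_t)out_h * ow);
      const double a00 = (1 - fh) * (1 - fw), a10 = fh * (1 - fw);
      const double a01 = (1 - fh) * fw, a11 = fh * fw;
      for (size_t i = 0; i < NC; ++i)
        dst[i] = a00 * p00[i] + a10 * p10[i] + a01 * p01[i] + a11 * p11[i];
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_backward(NumericVector gy, int in_h, int in_w) {
  IntegerVector gd = gy.attr("dim");
  const int N = gd[0], C = gd[1], OH = gd[2], OW = gd[3];
  NumericVector gx((size_t)N * C * in_h * in_w);
  gx.attr("dim") = IntegerVector::create(N, C, in_h, in_w);
  const size_t NC = (size_t)N * C;

  for (int ow = 0; ow < OW; ++ow) {
    int w0, w1; double fw;
    src_coord(ow, in_w, OW, w0, w1, fw);
    for (int oh = 0; oh < OH; ++oh) {
      int h0, h1; double fh;
      src_coord(oh, in_h, OH, h0, h1, fh);
      const double* src = gy.begin() + NC * (oh + (size_t)OH * ow);
      double* p00 = gx.begin() + NC * (h0 + (size_t)in_h * w0);
      double* p10 = gx.begin() + NC * (h1 + (size_t)in_h * w0);
      double* p01 = gx.begin() + NC * (h0 + (size_t)in_h * w1);
      double* p11 = gx.begin() + NC * (h1 + (size_t)in_h * w1);
      const double a00 = (1 - fh) * (1 - fw), a10 = fh * (1 - fw);
      const double a01 = (1 - fh) * fw, a11 = fh * fw;
      for (size_t i = 0; i < NC; ++i) {
        p00[i] += a00 * src[i];
        p10[i] += a10 * src[i];
        p01[i] += a01 * src[i];
        p11[i] += a11 * src[i];
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_nearest_resize(NumericVector x, int out_h, int out_w) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  NumericVector y((size_t)N * C * out_h * out_w);
  y.attr("dim") = IntegerVector::create(N, C, out_h, out_w);
  const size_t NC = (size_t)N * C;

  for (int ow = 0; ow < out_w; ++ow) {
    int w_in = (int)std::floor((ow + 0.5) * ((double)W / out_w));
    if (w_in > W - 1) w_in = W - 1;
    for (int oh = 0; oh < out_h; ++oh) {
      int h_in = (int)std::floor((oh + 0.5) * ((double)H / out_h));
      if (h_in > H - 1) h_in = H - 1;
      const double* src = x.begin() + NC * (h_in + (size_t)H * w_in);
      double* dst = y.begin() + NC * (oh + (size_t)out_h * ow);
      for (size_t i = 0; i < NC; ++i) dst[i] = src[i];
    }
  }
  return y;
}

// Separable Gaussian blur of a single-channel image (H x W matrix),
// reflect padding, truncated at 3 sigma. Used by the synthetic generator.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;

  NumericMatrix tmp(H, W), out(H, W);
  // vertical pass
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) {
        int hh = h + i;
        if (hh < 0) hh = -hh - 1;
        if (hh >= H) hh = 2 * H - hh - 1;
        acc += k[i + r] * img(hh, w);
      }
      tmp(h, w) = acc;
    }
  // horizontal pass
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) {
        int ww = w + i;
        if (ww < 0) ww = -ww - 1;
        if (ww >= W) ww = 2 * W - ww - 1;
        acc += k[i + r] * tmp(h, ww);
      }
      out(h, w) = acc;
    }
  return out;
}
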
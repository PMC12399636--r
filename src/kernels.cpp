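// Numeric kernels: dense/depthwise 2-D convolution with gradients,
// bilinear resampling, affine warping, orthographic mesh rasterization,
// brute-force nearest neighbours and a bilateral filter.
//
// Array convention throughout: feature maps are R arrays dim(H, W, C, N)
// (column-major), dense conv weights dim(kh, kw, Cin, Cout), depthwise
// weights dim(kh, kw, C).  All indices 0-based internally.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline arma::uword idx4(int h, int w, int c, int n,
                               int H, int W, int C) {
  return (arma::uword)h + (arma::uword)H * ((arma::uword)w +
         (arma::uword)W * ((arma::uword)c + (arma::uword)C * (arma::uword)n));
}

// im2col for one sample: returns (Hout*Wout) x (kh*kw*Cin)
static void im2col(const double* x, int H, int W, int C, int n,
                   int kh, int kw, int stride, int pad, int dil,
                   int Hout, int Wout, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int k = ki + kh * (kj + kw * c);
        double* dst = col.colptr(k);
        for (int wo = 0; wo < Wout; ++wo) {
          int wi = wo * stride - pad + kj * dil;
          for (int ho = 0; ho < Hout; ++ho) {
            int hi = ho * stride - pad + ki * dil;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              v = x[idx4(hi, wi, c, n, H, W, C)];
            dst[ho + Hout * wo] = v;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, double* gx,
                       int H, int W, int C, int n,
                       int kh, int kw, int stride, int pad, int dil,
                       int Hout, int Wout) {
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int k = ki + kh * (kj + kw * c);
        const double* src = col.colptr(k);
        for (int wo = 0; wo < Wout; ++wo) {
          int wi = wo * stride - pad + kj * dil;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Hout; ++ho) {
            int hi = ho * stride - pad + ki * dil;
            if (hi < 0 || hi >= H) continue;
            gx[idx4(hi, wi, c, n, H, W, C)] += src[ho + Hout * wo];
          }
        }
      }
    }
  }
}

static inline int out_size(int in, int k, int stride, int pad, int dil) {
  int eff = (k - 1) * dil + 1;
  return (in + 2 * pad - eff) / stride + 1;
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector bias,
                             int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  int Hout = out_size(H, kh, stride, pad, dil);
  int Wout = out_size(W, kw, stride, pad, dil);
  NumericVector y(R_xlen_t(Hout) * Wout * Cout * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  bool pointwise = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  arma::mat col;
  if (!pointwise) col.set_size(Hout * Wout, kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    arma::mat Y(y.begin() + idx4(0, 0, 0, n, Hout, Wout, Cout),
                Hout * Wout, Cout, false, true);
    if (pointwise) {
      const arma::mat X(const_cast<double*>(x.begin()) + idx4(0, 0, 0, n, H, W, C),
                        H * W, C, false, true);
      Y = X * Wm;
    } else {
      im2col(x.begin(), H, W, C, n, kh, kw, stride, pad, dil, Hout, Wout, col);
      Y = col * Wm;
    }
    for (int c = 0; c < Cout; ++c) Y.col(c) += bias[c];
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Hout = yd[0], Wout = yd[1];
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, Cout, false, true);
  arma::mat Gw(gw.begin(), kh * kw * C, Cout, false, true);
  bool pointwise = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  arma::mat col;
  if (!pointwise) col.set_size(Hout * Wout, kh * kw * C);
  for (int n = 0; n < N; ++n) {
    const arma::mat Gy(const_cast<double*>(gy.begin()) + idx4(0, 0, 0, n, Hout, Wout, Cout),
                       Hout * Wout, Cout, false, true);
    if (pointwise) {
      const arma::mat X(const_cast<double*>(x.begin()) + idx4(0, 0, 0, n, H, W, C),
                        H * W, C, false, true);
      arma::mat Gx(gx.begin() + idx4(0, 0, 0, n, H, W, C), H * W, C, false, true);
      Gx += Gy * Wm.t();
      Gw += X.t() * Gy;
    } else {
      im2col(x.begin(), H, W, C, n, kh, kw, stride, pad, dil, Hout, Wout, col);
      Gw += col.t() * Gy;
      arma::mat gcol = Gy * Wm.t();
      col2im_add(gcol, gx.begin(), H, W, C, n, kh, kw, stride, pad, dil, Hout, Wout);
    }
    for (int c = 0; c < Cout; ++c) gb[c] += arma::accu(Gy.col(c));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".cpp_dwconv_fwd")]]
NumericVector cpp_dwconv_fwd(NumericVector x, NumericVector w,
                             NumericVector bias,
                             int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1];
  int Hout = out_size(H, kh, stride, pad, dil);
  int Wout = out_size(W, kw, stride, pad, dil);
  NumericVector y(R_xlen_t(Hout) * Wout * C * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
      double* yc = yp + ((R_xlen_t)c + (R_xlen_t)C * n) * Hout * Wout;
      const double* wc = w.begin() + (R_xlen_t)kh * kw * c;
      double bv = bias[c];
      std::fill(yc, yc + (R_xlen_t)Hout * Wout, bv);
      for (int wo = 0; wo < Wout; ++wo) {
        double* ycol = yc + (R_xlen_t)wo * Hout;
        for (int kj = 0; kj < kw; ++kj) {
          int wi = wo * stride - pad + kj * dil;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xc + (R_xlen_t)wi * H;
          for (int ki = 0; ki < kh; ++ki) {
            double wv = wc[ki + kh * kj];
            int off = -pad + ki * dil;
            int ho0 = std::max(0, (int)std::ceil((-off) / (double)stride));
            int ho1 = std::min(Hout - 1, (H - 1 - off) / stride);
            const double* xs = xcol + off + (R_xlen_t)ho0 * stride;
            if (stride == 1) {
              for (int ho = ho0; ho <= ho1; ++ho, ++xs)
                ycol[ho] += wv * (*xs);
            } else {
              for (int ho = ho0; ho <= ho1; ++ho, xs += stride)
                ycol[ho] += wv * (*xs);
            }
          }
        }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".cpp_dwconv_bwd")]]
List cpp_dwconv_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1];
  int Hout = yd[0], Wout = yd[1];
  NumericVector gx(x.size());  gx.attr("dim") = xd;
  NumericVector gw(w.size());  gw.attr("dim") = wd;
  NumericVector gb(C);
  const double* xp = x.begin();
  const double* gyp = gy.begin();
  double* gxp = gx.begin();
  double* gwp = gw.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
      double* gxc = gxp + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
      const double* gc = gyp + ((R_xlen_t)c + (R_xlen_t)C * n) * Hout * Wout;
      const double* wc = w.begin() + (R_xlen_t)kh * kw * c;
      double* gwc = gwp + (R_xlen_t)kh * kw * c;
      double bsum = 0;
      for (R_xlen_t i = 0; i < (R_xlen_t)Hout * Wout; ++i) bsum += gc[i];
      gb[c] += bsum;
      for (int wo = 0; wo < Wout; ++wo) {
        const double* gcol = gc + (R_xlen_t)wo * Hout;
        for (int kj = 0; kj < kw; ++kj) {
          int wi = wo * stride - pad + kj * dil;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xc + (R_xlen_t)wi * H;
          double* gxcol = gxc + (R_xlen_t)wi * H;
          for (int ki = 0; ki < kh; ++ki) {
            double wv = wc[ki + kh * kj];
            double acc = 0;
            int off = -pad + ki * dil;
            int ho0 = std::max(0, (int)std::ceil((-off) / (double)stride));
            int ho1 = std::min(Hout - 1, (H - 1 - off) / stride);
            const double* xs = xcol + off + (R_xlen_t)ho0 * stride;
            double* gs = gxcol + off + (R_xlen_t)ho0 * stride;
            for (int ho = ho0; ho <= ho1; ++ho, xs += stride, gs += stride) {
              double g = gcol[ho];
              *gs += wv * g;
              acc += g * (*xs);
            }
            gwc[ki + kh * kj] += acc;
          }
        }
      }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---- batch norm and activation kernels -------------------------------------

// per-channel sums and sums of squares over (H, W, N)
// [[Rcpp::export(name = ".cpp_channel_stats")]]
List cpp_channel_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector s(C), s2(C);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
      double a = 0, b = 0;
      for (R_xlen_t i = 0; i < (R_xlen_t)H * W; ++i) {
        a += xc[i];
        b += xc[i] * xc[i];
      }
      s[c] += a; s2[c] += b;
    }
  return List::create(_["sum"] = s, _["sumsq"] = s2);
}

// y = gamma * (x - mu) * ivar + beta, optionally clamped to [0, 6]
// (fused ReLU6)
// [[Rcpp::export(name = ".cpp_bn_fwd")]]
NumericVector cpp_bn_fwd(NumericVector x, NumericVector mu,
                         NumericVector ivar, NumericVector gamma,
                         NumericVector beta, bool relu6) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      R_xlen_t base = ((R_xlen_t)c + (R_xlen_t)C * n) * H * W;
      double m = mu[c], iv = ivar[c], g = gamma[c], b = beta[c];
      for (R_xlen_t i = 0; i < (R_xlen_t)H * W; ++i) {
        double v = g * (xp[base + i] - m) * iv + b;
        if (relu6) v = v < 0 ? 0 : (v > 6 ? 6 : v);
        yp[base + i] = v;
      }
    }
  return y;
}

// standard batch-norm backward; xhat is recomputed on the fly from the
// stored convolution output x. When y is supplied the fused-ReLU6 mask
// (0 < y < 6) gates the incoming gradient.
// [[Rcpp::export(name = ".cpp_bn_bwd")]]
List cpp_bn_bwd(NumericVector x, NumericVector mu, NumericVector g,
                NumericVector gamma, NumericVector ivar, bool need_gx,
                Nullable<NumericVector> y_relu = R_NilValue) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  R_xlen_t hw = (R_xlen_t)H * W;
  double m = (double)hw * N;
  NumericVector dgamma(C), dbeta(C);
  const double* xp = x.begin();
  const double* gp0 = g.begin();
  const double* yp = nullptr;
  NumericVector gm;
  if (y_relu.isNotNull()) {
    NumericVector yv(y_relu);
    yp = yv.begin();
    gm = NumericVector(g.size());
    double* t = gm.begin();
    for (R_xlen_t i = 0; i < g.size(); ++i) {
      t[i] = (yp[i] > 0 && yp[i] < 6) ? gp0[i] : 0;
    }
    gm.attr("dim") = xd;
    gp0 = gm.begin();
  }
  const double* gp = gp0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      R_xlen_t base = ((R_xlen_t)c + (R_xlen_t)C * n) * hw;
      double a = 0, b = 0, mc = mu[c], iv = ivar[c];
      for (R_xlen_t i = 0; i < hw; ++i) {
        a += gp[base + i] * (xp[base + i] - mc) * iv;
        b += gp[base + i];
      }
      dgamma[c] += a; dbeta[c] += b;
    }
  if (!need_gx) {
    return List::create(_["dgamma"] = dgamma, _["dbeta"] = dbeta);
  }
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  double* gxp = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      R_xlen_t base = ((R_xlen_t)c + (R_xlen_t)C * n) * hw;
      double s1 = dbeta[c] / m, s2 = dgamma[c] / m;
      double giv = gamma[c] * ivar[c];
      double mc = mu[c], iv = ivar[c];
      for (R_xlen_t i = 0; i < hw; ++i) {
        double xh = (xp[base + i] - mc) * iv;
        gxp[base + i] = giv * (gp[base + i] - s1 - xh * s2);
      }
    }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".cpp_relu6_fwd")]]
NumericVector cpp_relu6_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = xp[i];
    yp[i] = v < 0 ? 0 : (v > 6 ? 6 : v);
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_relu6_bwd")]]
NumericVector cpp_relu6_bwd(NumericVector x, NumericVector g) {
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* op = gx.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    op[i] = (xp[i] > 0 && xp[i] < 6) ? gp[i] : 0;
  }
  return gx;
}

// Bilinear interpolation weights for align_corners = FALSE sampling.
static inline void lin_coeff(int out, int in, int o, int& i0, int& i1,
                             double& w0, double& w1) {
  double scale = (double)in / out;
  double pos = (o + 0.5) * scale - 0.5;
  if (pos < 0) pos = 0;
  if (pos > in - 1) pos = in - 1;
  i0 = (int)std::floor(pos);
  i1 = std::min(i0 + 1, in - 1);
  w1 = pos - i0;
  w0 = 1.0 - w1;
}

// [[Rcpp::export(name = ".cpp_upsample_fwd")]]
NumericVector cpp_upsample_fwd(NumericVector x, int Hout, int Wout) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(R_xlen_t(Hout) * Wout * C * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  std::vector<int> h0(Hout), h1(Hout), w0i(Wout), w1i(Wout);
  std::vector<double> ha(Hout), hb(Hout), wa(Wout), wb(Wout);
  for (int i = 0; i < Hout; ++i) lin_coeff(Hout, H, i, h0[i], h1[i], ha[i], hb[i]);
  for (int j = 0; j < Wout; ++j) lin_coeff(Wout, W, j, w0i[j], w1i[j], wa[j], wb[j]);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wout; ++j)
        for (int i = 0; i < Hout; ++i) {
          double v =
            wa[j] * (ha[i] * xp[idx4(h0[i], w0i[j], c, n, H, W, C)] +
                     hb[i] * xp[idx4(h1[i], w0i[j], c, n, H, W, C)]) +
            wb[j] * (ha[i] * xp[idx4(h0[i], w1i[j], c, n, H, W, C)] +
                     hb[i] * xp[idx4(h1[i], w1i[j], c, n, H, W, C)]);
          yp[idx4(i, j, c, n, Hout, Wout, C)] = v;
        }
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample_bwd")]]
NumericVector cpp_upsample_bwd(NumericVector gy, int H, int W) {
  IntegerVector yd = gy.attr("dim");
  int Hout = yd[0], Wout = yd[1], C = yd[2], N = yd[3];
  NumericVector gx(R_xlen_t(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gyp = gy.begin();
  double* gxp = gx.begin();
  std::vector<int> h0(Hout), h1(Hout), w0i(Wout), w1i(Wout);
  std::vector<double> ha(Hout), hb(Hout), wa(Wout), wb(Wout);
  for (int i = 0; i < Hout; ++i) lin_coeff(Hout, H, i, h0[i], h1[i], ha[i], hb[i]);
  for (int j = 0; j < Wout; ++j) lin_coeff(Wout, W, j, w0i[j], w1i[j], wa[j], wb[j]);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wout; ++j)
        for (int i = 0; i < Hout; ++i) {
          double g = gyp[idx4(i, j, c, n, Hout, Wout, C)];
          gxp[idx4(h0[i], w0i[j], c, n, H, W, C)] += wa[j] * ha[i] * g;
          gxp[idx4(h1[i], w0i[j], c, n, H, W, C)] += wa[j] * hb[i] * g;
          gxp[idx4(h0[i], w1i[j], c, n, H, W, C)] += wb[j] * ha[i] * g;
          gxp[idx4(h1[i], w1i[j], c, n, H, W, C)] += wb[j] * hb[i] * g;
        }
  return gx;
}

// Affine warp of a single-channel image.  A maps output (x,y) pixel
// coordinates (0-based, x = column) to input coordinates:
// src = A[1:2,1:2] %*% c(x,y) + A[,3].
// [[Rcpp::export(name = ".cpp_warp_affine")]]
NumericMatrix cpp_warp_affine(NumericMatrix img, NumericMatrix A,
                              bool nearest, double fill) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  double a11 = A(0, 0), a12 = A(0, 1), tx = A(0, 2);
  double a21 = A(1, 0), a22 = A(1, 1), ty = A(1, 2);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double sx = a11 * x + a12 * y + tx;
      double sy = a21 * x + a22 * y + ty;
      double v = fill;
      if (nearest) {
        int ix = (int)std::lround(sx), iy = (int)std::lround(sy);
        if (ix >= 0 && ix < W && iy >= 0 && iy < H) v = img(iy, ix);
      } else if (sx >= 0 && sx <= W - 1 && sy >= 0 && sy <= H - 1) {
        int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
        int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
        double fx = sx - x0, fy = sy - y0;
        v = (1 - fx) * ((1 - fy) * img(y0, x0) + fy * img(y1, x0)) +
            fx * ((1 - fy) * img(y0, x1) + fy * img(y1, x1));
      }
      out(y, x) = v;
    }
  return out;
}

// Orthographic z-buffer rasterization.  V: n x 3 vertices already in view
// coordinates (u, v, d) in pixels/units where u = column coord, v = row
// coord (both in pixel units, 0-based), d = depth along the view ray
// (smaller = closer).  F: m x 3 0-based triangle indices.
// Returns H x W depth matrix, NA where empty.
// [[Rcpp::export(name = ".cpp_rasterize")]]
NumericMatrix cpp_rasterize(NumericMatrix V, IntegerMatrix F, int H, int W) {
  NumericMatrix depth(H, W);
  std::fill(depth.begin(), depth.end(), NA_REAL);
  int m = F.nrow();
  for (int t = 0; t < m; ++t) {
    int i0 = F(t, 0), i1 = F(t, 1), i2 = F(t, 2);
    double x0 = V(i0, 0), y0 = V(i0, 1), d0 = V(i0, 2);
    double x1 = V(i1, 0), y1 = V(i1, 1), d1 = V(i1, 2);
    double x2 = V(i2, 0), y2 = V(i2, 1), d2 = V(i2, 2);
    int xmin = std::max(0, (int)std::floor(std::min({x0, x1, x2})));
    int xmax = std::min(W - 1, (int)std::ceil(std::max({x0, x1, x2})));
    int ymin = std::max(0, (int)std::floor(std::min({y0, y1, y2})));
    int ymax = std::min(H - 1, (int)std::ceil(std::max({y0, y1, y2})));
    double den = (y1 - y2) * (x0 - x2) + (x2 - x1) * (y0 - y2);
    if (std::fabs(den) < 1e-12) continue;
    for (int y = ymin; y <= ymax; ++y)
      for (int x = xmin; x <= xmax; ++x) {
        double l0 = ((y1 - y2) * (x - x2) + (x2 - x1) * (y - y2)) / den;
        double l1 = ((y2 - y0) * (x - x2) + (x0 - x2) * (y - y2)) / den;
        double l2 = 1.0 - l0 - l1;
        const double eps = -1e-9;
        if (l0 < eps || l1 < eps || l2 < eps) continue;
        double d = l0 * d0 + l1 * d1 + l2 * d2;
        double cur = depth(y, x);
        if (NumericMatrix::is_na(cur) || d < cur) depth(y, x) = d;
      }
  }
  return depth;
}

// Brute-force nearest neighbour: for each row of Q find nearest row of R.
// [[Rcpp::export(name = ".cpp_nn_index")]]
List cpp_nn_index(NumericMatrix Q, NumericMatrix R) {
  int nq = Q.nrow(), nr = R.nrow(), d = Q.ncol();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    int bi = 0;
    for (int j = 0; j < nr; ++j) {
      double s = 0;
      for (int k = 0; k < d; ++k) {
        double diff = Q(i, k) - R(j, k);
        s += diff * diff;
      }
      if (s < best) { best = s; bi = j; }
    }
    idx[i] = bi + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// Bilateral filter on a single-channel image (values on any scale).
// [[Rcpp::export(name = ".cpp_bilateral")]]
NumericMatrix cpp_bilateral(NumericMatrix img, int d,
                            double sigma_color, double sigma_space) {
  int H = img.nrow(), W = img.ncol();
  int r = d / 2;
  NumericMatrix out(H, W);
  std::vector<double> sw((2 * r + 1) * (2 * r + 1));
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx)
      sw[(dy + r) * (2 * r + 1) + (dx + r)] =
        std::exp(-(dx * dx + dy * dy) / (2.0 * sigma_space * sigma_space));
  double ic2 = 2.0 * sigma_color * sigma_color;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double c0 = img(y, x), num = 0, den = 0;
      for (int dy = -r; dy <= r; ++dy) {
        int yy = y + dy;
        if (yy < 0 || yy >= H) continue;
        for (int dx = -r; dx <= r; ++dx) {
          int xx = x + dx;
          if (xx < 0 || xx >= W) continue;
          double v = img(yy, xx);
          double wgt = sw[(dy + r) * (2 * r + 1) + (dx + r)] *
                       std::exp(-(v - c0) * (v - c0) / ic2);
          num += wgt * v;
          den += wgt;
        }
      }
      out(y, x) = num / den;
    }
  return out;
}
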
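// Low-level tensor ops for the dense-block U-Net.
//
// Activation layout everywhere: numeric array with dim c(H, W, C, N),
// column-major (R native), i.e. element (h, w, c, n) sits at
// h + H*(w + W*(c + C*n)), all indices 0-based here.
//
// Convolutions use zero padding ("same", stride 1, odd kernel). 3x3 convs
// are computed per sample as an im2col gather (contiguous memcpy spans)
// followed by a BLAS gemm; 1x1 convs skip the gather and multiply the
// (H*W) x C activation matrix directly. The backward pass re-gathers the
// patch matrix instead of caching it, trading FLOPs for memory.

#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;

// Gather one sample into col: (H*W) x (K*K*C); column j = (kh, kw, c) with
// kh fastest, matching the column-major flattening of an R weight array
// dim c(K, K, C, Co). Interior spans are plain memcpy.
static void im2col(const double* xn, int H, int W, int C, int K,
                   arma::mat& col) {
  const int P = K / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = xn + (size_t)H * W * c;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        double* dst = col.colptr(kh + K * (kw + K * c));
        const int dh = kh - P, dw = kw - P;
        const int h0 = dh < 0 ? -dh : 0;        // first valid output row
        const int len = H - (dh < 0 ? -dh : dh);  // valid span length
        for (int w = 0; w < W; ++w) {
          double* d = dst + (size_t)H * w;
          const int sw = w + dw;
          if (sw < 0 || sw >= W) {
            std::memset(d, 0, sizeof(double) * H);
            continue;
          }
          const double* s = xc + (size_t)H * sw + (h0 + dh);
          if (h0 > 0) std::memset(d, 0, sizeof(double) * h0);
          std::memcpy(d + h0, s, sizeof(double) * len);
          if (h0 + len < H)
            std::memset(d + h0 + len, 0, sizeof(double) * (H - h0 - len));
        }
      }
    }
  }
}

// Scatter-add the column gradient back onto the (H, W, C) sample grid.
static void col2im_add(const arma::mat& gcol, int H, int W, int C, int K,
                       double* gxn) {
  const int P = K / 2;
  for (int c = 0; c < C; ++c) {
    double* gc = gxn + (size_t)H * W * c;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const double* src = gcol.colptr(kh + K * (kw + K * c));
        const int dh = kh - P, dw = kw - P;
        const int h0 = dh < 0 ? -dh : 0;
        const int len = H - (dh < 0 ? -dh : dh);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          double* d = gc + (size_t)H * sw + (h0 + dh);
          const double* s = src + (size_t)H * w + h0;
          for (int h = 0; h < len; ++h) d[h] += s[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], Co = wd[3];
  if (wd[2] != C) stop("conv: weight Cin %d != input C %d", (int)wd[2], C);
  arma::mat Wm(const_cast<double*>(w.begin()), K * K * C, Co, false, true);
  NumericVector y((size_t)H * W * Co * N);
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  arma::mat col;
  if (K > 1) col.set_size((size_t)H * W, K * K * C);
  for (int n = 0; n < N; ++n) {
    arma::mat Y(y.begin() + (size_t)H * W * Co * n, (size_t)H * W, Co,
                false, true);
    if (K == 1) {
      const arma::mat X(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                        (size_t)H * W, C, false, true);
      Y = X * Wm;
    } else {
      im2col(x.begin() + (size_t)H * W * C * n, H, W, C, K, col);
      Y = col * Wm;
    }
    for (int co = 0; co < Co; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], Co = wd[3];
  arma::mat Wm(const_cast<double*>(w.begin()), K * K * C, Co, false, true);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xd;
  NumericVector gw((size_t)K * K * C * Co);
  gw.attr("dim") = wd;
  NumericVector gb(Co);
  arma::mat Gw(gw.begin(), K * K * C, Co, false, true);
  arma::mat col;
  if (K > 1) col.set_size((size_t)H * W, K * K * C);
  for (int n = 0; n < N; ++n) {
    arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)H * W * Co * n,
                 (size_t)H * W, Co, false, true);
    if (K == 1) {
      const arma::mat X(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                        (size_t)H * W, C, false, true);
      Gw += X.t() * Gy;
      arma::mat Gx(gx.begin() + (size_t)H * W * C * n, (size_t)H * W, C,
                   false, true);
      Gx = Gy * Wm.t();
    } else {
      im2col(x.begin() + (size_t)H * W * C * n, H, W, C, K, col);
      Gw += col.t() * Gy;
      arma::mat gcol = Gy * Wm.t();
      col2im_add(gcol, H, W, C, K, gx.begin() + (size_t)H * W * C * n);
    }
    for (int co = 0; co < Co; ++co) gb[co] += arma::accu(Gy.col(co));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 stride-2 transposed convolution: (H, W, Ci, N) -> (2H, 2W, Co, N).
// w has dim c(2, 2, Ci, Co).

// [[Rcpp::export]]
NumericVector nn_convt_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int Co = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      double* yc = y.begin() + (size_t)Ho * Wo * (co + (size_t)Co * n);
      std::fill(yc, yc + (size_t)Ho * Wo, b[co]);
      for (int ci = 0; ci < Ci; ++ci) {
        const double* xc =
            x.begin() + (size_t)H * W * (ci + (size_t)Ci * n);
        const double* wk = w.begin() + 4 * (ci + (size_t)Ci * co);
        const double w00 = wk[0], w10 = wk[1], w01 = wk[2], w11 = wk[3];
        for (int ww = 0; ww < W; ++ww) {
          const double* xcol = xc + (size_t)H * ww;
          double* y0 = yc + (size_t)Ho * (2 * ww);
          double* y1 = y0 + Ho;
          for (int h = 0; h < H; ++h) {
            const double v = xcol[h];
            y0[2 * h] += v * w00;
            y0[2 * h + 1] += v * w10;
            y1[2 * h] += v * w01;
            y1[2 * h + 1] += v * w11;
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_convt_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int Co = wd[3];
  const int Ho = 2 * H;
  NumericVector gx((size_t)H * W * Ci * N);
  gx.attr("dim") = xd;
  NumericVector gw((size_t)4 * Ci * Co);
  gw.attr("dim") = wd;
  NumericVector gb(Co);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      const double* gyc =
          gy.begin() + (size_t)Ho * 2 * W * (co + (size_t)Co * n);
      double s = 0.0;
      for (size_t i = 0; i < (size_t)Ho * 2 * W; ++i) s += gyc[i];
      gb[co] += s;
      for (int ci = 0; ci < Ci; ++ci) {
        const double* xc =
            x.begin() + (size_t)H * W * (ci + (size_t)Ci * n);
        double* gxc = gx.begin() + (size_t)H * W * (ci + (size_t)Ci * n);
        double* gwk = gw.begin() + 4 * (ci + (size_t)Ci * co);
        const double* wk = w.begin() + 4 * (ci + (size_t)Ci * co);
        double a00 = 0, a10 = 0, a01 = 0, a11 = 0;
        for (int ww = 0; ww < W; ++ww) {
          const double* g0 = gyc + (size_t)Ho * (2 * ww);
          const double* g1 = g0 + Ho;
          const double* xcol = xc + (size_t)H * ww;
          double* gcol = gxc + (size_t)H * ww;
          for (int h = 0; h < H; ++h) {
            const double v = xcol[h];
            const double b00 = g0[2 * h], b10 = g0[2 * h + 1];
            const double b01 = g1[2 * h], b11 = g1[2 * h + 1];
            a00 += v * b00;
            a10 += v * b10;
            a01 += v * b01;
            a11 += v * b11;
            gcol[h] += wk[0] * b00 + wk[1] * b10 + wk[2] * b01 + wk[3] * b11;
          }
        }
        gwk[0] += a00;
        gwk[1] += a10;
        gwk[2] += a01;
        gwk[3] += a11;
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 stride-2 average pooling.

// [[Rcpp::export]]
NumericVector nn_avgpool_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* xp = x.begin() + (size_t)H * W * p;
    double* yp = y.begin() + (size_t)Ho * Wo * p;
    for (int w = 0; w < Wo; ++w) {
      const double* c0 = xp + (size_t)H * (2 * w);
      const double* c1 = xp + (size_t)H * (2 * w + 1);
      for (int h = 0; h < Ho; ++h)
        yp[h + (size_t)Ho * w] =
            0.25 * (c0[2 * h] + c0[2 * h + 1] + c1[2 * h] + c1[2 * h + 1]);
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_avgpool_bw(NumericVector gy, int H, int W) {
  IntegerVector yd = gy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* gp = gy.begin() + (size_t)Ho * Wo * p;
    double* xp = gx.begin() + (size_t)H * W * p;
    for (int w = 0; w < Wo; ++w) {
      double* c0 = xp + (size_t)H * (2 * w);
      double* c1 = xp + (size_t)H * (2 * w + 1);
      for (int h = 0; h < Ho; ++h) {
        const double g = 0.25 * gp[h + (size_t)Ho * w];
        c0[2 * h] = g;
        c0[2 * h + 1] = g;
        c1[2 * h] = g;
        c1[2 * h + 1] = g;
      }
    }
  }
  return gx;
}

// Fused batch normalization (per channel over H, W, N) + ReLU.
// Returns the post-ReLU activation; the backward op reconstructs the ReLU
// mask from it, so nothing else needs caching beyond x, mu, var.

// [[Rcpp::export]]
List nn_bnrelu_fw(NumericVector x, NumericVector gamma, NumericVector beta,
                  double eps, bool training, NumericVector rmean,
                  NumericVector rvar, double momentum) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t hw = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  NumericVector mu(C), var(C), nrmean = clone(rmean), nrvar = clone(rvar);
  const double m = (double)hw * N;
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xp = x.begin() + hw * (c + (size_t)C * n);
        for (size_t i = 0; i < hw; ++i) {
          s += xp[i];
          s2 += xp[i] * xp[i];
        }
      }
      mu[c] = s / m;
      var[c] = s2 / m - mu[c] * mu[c];
      if (var[c] < 0) var[c] = 0;
      nrmean[c] = (1 - momentum) * rmean[c] + momentum * mu[c];
      nrvar[c] = (1 - momentum) * rvar[c] + momentum * var[c];
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mu[c] = rmean[c];
      var[c] = rvar[c];
    }
  }
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], bta = beta[c], mc = mu[c];
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + hw * (c + (size_t)C * n);
      double* yp = y.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) {
        const double v = g * (xp[i] - mc) * inv + bta;
        yp[i] = v > 0 ? v : 0;
      }
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["var"] = var,
                      _["rmean"] = nrmean, _["rvar"] = nrvar);
}

// [[Rcpp::export]]
List nn_bnrelu_bw(NumericVector x, NumericVector a, NumericVector gamma,
                  NumericVector mu, NumericVector var, double eps,
                  NumericVector gy) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t hw = (size_t)H * W;
  const double m = (double)hw * N;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double mc = mu[c];
    double sdg = 0.0, sdb = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + hw * (c + (size_t)C * n);
      const double* ap = a.begin() + hw * (c + (size_t)C * n);
      const double* gp = gy.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) {
        const double g = ap[i] > 0 ? gp[i] : 0.0;  // ReLU gate
        sdg += g * (xp[i] - mc) * inv;
        sdb += g;
      }
    }
    dgamma[c] = sdg;
    dbeta[c] = sdb;
    // dx = gamma*inv/m * (m*gy - sum(gy) - xhat * sum(gy*xhat))
    const double k = gamma[c] * inv / m;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + hw * (c + (size_t)C * n);
      const double* ap = a.begin() + hw * (c + (size_t)C * n);
      const double* gp = gy.begin() + hw * (c + (size_t)C * n);
      double* dp = gx.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) {
        const double g = ap[i] > 0 ? gp[i] : 0.0;
        const double xhat = (xp[i] - mc) * inv;
        dp[i] = k * (m * g - sdb - xhat * sdg);
      }
    }
  }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Channel concatenation along dim 3 of (H, W, C, N) arrays.

// [[Rcpp::export]]
NumericVector nn_concat(NumericVector a, NumericVector b) {
  IntegerVector ad = a.attr("dim"), bd = b.attr("dim");
  const int H = ad[0], W = ad[1], Ca = ad[2], N = ad[3], Cb = bd[2];
  if (bd[0] != H || bd[1] != W || bd[3] != N)
    stop("concat: incompatible shapes");
  const size_t hw = (size_t)H * W;
  NumericVector y(hw * (Ca + Cb) * N);
  y.attr("dim") = IntegerVector::create(H, W, Ca + Cb, N);
  for (int n = 0; n < N; ++n) {
    std::copy(a.begin() + hw * Ca * n, a.begin() + hw * Ca * (n + 1),
              y.begin() + hw * (Ca + Cb) * n);
    std::copy(b.begin() + hw * Cb * n, b.begin() + hw * Cb * (n + 1),
              y.begin() + hw * (Ca + Cb) * n + hw * Ca);
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_slice_channels(NumericVector x, int from, int to) {
  // 1-based inclusive channel range.
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Cs = to - from + 1;
  const size_t hw = (size_t)H * W;
  NumericVector y(hw * Cs * N);
  y.attr("dim") = IntegerVector::create(H, W, Cs, N);
  for (int n = 0; n < N; ++n)
    std::copy(x.begin() + hw * ((size_t)C * n + from - 1),
              x.begin() + hw * ((size_t)C * n + to),
              y.begin() + hw * (size_t)Cs * n);
  return y;
}
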
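// Pixel-neighbourhood operators used by the enhancement pipeline.

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

static inline int reflect(int i, int n) {
  // symmetric reflection with edge duplication: (dcba | abcd | dcba)
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static inline int clampi(int i, int n) {
  return i < 0 ? 0 : (i >= n ? n - 1 : i);
}

// [[Rcpp::export]]
NumericMatrix img_median(NumericMatrix x, int k) {
  const int H = x.nrow(), W = x.ncol(), r = k / 2;
  NumericMatrix y(H, W);
  std::vector<double> buf(k * k);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      int m = 0;
      for (int dw = -r; dw <= r; ++dw) {
        const int sw = reflect(w + dw, W);
        for (int dh = -r; dh <= r; ++dh)
          buf[m++] = x(reflect(h + dh, H), sw);
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
      y(h, w) = buf[m / 2];
    }
  }
  return y;
}

// Grayscale erosion/dilation over an arbitrary offset set (flat structuring
// element), replicate border.

// [[Rcpp::export]]
NumericMatrix img_erode(NumericMatrix x, IntegerMatrix off) {
  const int H = x.nrow(), W = x.ncol(), M = off.nrow();
  NumericMatrix y(H, W);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double v = R_PosInf;
      for (int m = 0; m < M; ++m) {
        const double u = x(clampi(h + off(m, 0), H), clampi(w + off(m, 1), W));
        if (u < v) v = u;
      }
      y(h, w) = v;
    }
  return y;
}

// [[Rcpp::export]]
NumericMatrix img_dilate(NumericMatrix x, IntegerMatrix off) {
  const int H = x.nrow(), W = x.ncol(), M = off.nrow();
  NumericMatrix y(H, W);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double v = R_NegInf;
      for (int m = 0; m < M; ++m) {
        const double u = x(clampi(h + off(m, 0), H), clampi(w + off(m, 1), W));
        if (u > v) v = u;
      }
      y(h, w) = v;
    }
  return y;
}
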
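// Hot loops of the convolution layers: im2col / col2im patch extraction.
// Feature maps are R arrays dim (H, W, C), column-major; the patch matrix has
// one row per output position (oh + outH*ow) and one column per kernel tap
// (kh + k*kw + k*k*c), so a convolution is a single matrix product in R.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  const int outH = (H + 2 * pad - k) / stride + 1;
  const int outW = (W + 2 * pad - k) / stride + 1;
  NumericMatrix cols(outH * outW, k * k * C);
  double *out = cols.begin();
  const double *in = x.begin();
  for (int c = 0; c < C; ++c) {
    const double *plane = in + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        double *col = out + (size_t)(kh + k * kw + k * k * c) * outH * outW;
        for (int ow = 0; ow < outW; ++ow) {
          const int w = ow * stride - pad + kw;
          double *dst = col + (size_t)outH * ow;
          if (w < 0 || w >= W) {
            for (int oh = 0; oh < outH; ++oh) dst[oh] = 0.0;
            continue;
          }
          const double *src = plane + (size_t)H * w;
          for (int oh = 0; oh < outH; ++oh) {
            const int h = oh * stride - pad + kh;
            dst[oh] = (h >= 0 && h < H) ? src[h] : 0.0;
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  const int outH = (H + 2 * pad - k) / stride + 1;
  const int outW = (W + 2 * pad - k) / stride + 1;
  NumericVector x((size_t)H * W * C);
  double *out = x.begin();
  const double *in = cols.begin();
  for (int c = 0; c < C; ++c) {
    double *plane = out + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const double *col = in + (size_t)(kh + k * kw + k * k * c) * outH * outW;
        for (int ow = 0; ow < outW; ++ow) {
          const int w = ow * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          double *dst = plane + (size_t)H * w;
          const double *src = col + (size_t)outH * ow;
          for (int oh = 0; oh < outH; ++oh) {
            const int h = oh * stride - pad + kh;
            if (h >= 0 && h < H) dst[h] += src[oh];
          }
        }
      }
    }
  }
  return x;
}
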
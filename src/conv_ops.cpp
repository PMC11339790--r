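#include <Rcpp.h>
using namespace Rcpp;

// Tensors are R arrays with dim (H, W, C, N), column-major.
// im2col lowers a convolution to a GEMM: the returned matrix has one row per
// (kernel row, kernel col, input channel) -- matching the natural flattening
// of a weight array with dim (kh, kw, Cin, Cout) -- and one column per
// (output row, output col, sample), output row fastest.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad) {
  const int oh = (H + 2 * pad - kh) / stride + 1;
  const int ow = (W + 2 * pad - kw) / stride + 1;
  const int rows = kh * kw * C;
  NumericMatrix out(rows, oh * ow * (R_xlen_t)N);
  const double* px = x.begin();
  double* po = out.begin();
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  const R_xlen_t planeHWC = planeHW * C;

  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < ow; ++wo) {
      for (int ho = 0; ho < oh; ++ho) {
        R_xlen_t col = ((R_xlen_t)n * ow + wo) * oh + ho;
        double* dst = po + col * rows;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double* src = px + (R_xlen_t)n * planeHWC + (R_xlen_t)c * planeHW;
          for (int kj = 0; kj < kw; ++kj) {
            const int w = w0 + kj;
            double* d = dst + (R_xlen_t)c * kh * kw + (R_xlen_t)kj * kh;
            if (w < 0 || w >= W) {
              for (int ki = 0; ki < kh; ++ki) d[ki] = 0.0;
            } else {
              const double* s = src + (R_xlen_t)w * H;
              for (int ki = 0; ki < kh; ++ki) {
                const int h = h0 + ki;
                d[ki] = (h < 0 || h >= H) ? 0.0 : s[h];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add columns back onto the input grid.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad) {
  const int oh = (H + 2 * pad - kh) / stride + 1;
  const int ow = (W + 2 * pad - kw) / stride + 1;
  const int rows = kh * kw * C;
  NumericVector x((R_xlen_t)H * W * C * N);
  double* px = x.begin();
  const double* pc = cols.begin();
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  const R_xlen_t planeHWC = planeHW * C;

  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < ow; ++wo) {
      for (int ho = 0; ho < oh; ++ho) {
        R_xlen_t col = ((R_xlen_t)n * ow + wo) * oh + ho;
        const double* src = pc + col * rows;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          double* dstp = px + (R_xlen_t)n * planeHWC + (R_xlen_t)c * planeHW;
          for (int kj = 0; kj < kw; ++kj) {
            const int w = w0 + kj;
            if (w < 0 || w >= W) continue;
            const double* s = src + (R_xlen_t)c * kh * kw + (R_xlen_t)kj * kh;
            double* d = dstp + (R_xlen_t)w * H;
            for (int ki = 0; ki < kh; ++ki) {
              const int h = h0 + ki;
              if (h >= 0 && h < H) d[h] += s[ki];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}

// Max pooling; records the argmax (1-based linear index into the input array)
// so the backward pass can route gradients.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int H, int W, int C, int N,
                     int k, int stride, int pad) {
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  NumericVector out((R_xlen_t)oh * ow * C * N);
  IntegerVector arg((R_xlen_t)oh * ow * C * N);
  const double* px = x.begin();
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  const R_xlen_t planeHWC = planeHW * C;
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* src = px + (R_xlen_t)n * planeHWC + (R_xlen_t)c * planeHW;
      for (int wo = 0; wo < ow; ++wo) {
        for (int ho = 0; ho < oh; ++ho) {
          double best = R_NegInf;
          R_xlen_t besti = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int w = wo * stride - pad + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int h = ho * stride - pad + ki;
              if (h < 0 || h >= H) continue;
              const double v = src[(R_xlen_t)w * H + h];
              if (v > best) {
                best = v;
                besti = (R_xlen_t)n * planeHWC + (R_xlen_t)c * planeHW +
                        (R_xlen_t)w * H + h;
              }
            }
          }
          // column-major output index: (ho, wo, c, n)
          R_xlen_t oi = ho + (R_xlen_t)oh * wo + (R_xlen_t)oh * ow * c +
                        (R_xlen_t)oh * ow * C * n;
          out[oi] = best;
          arg[oi] = (int)(besti + 1);
          ++o;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(oh, ow, C, N);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dout, IntegerVector argmax,
                              int H, int W, int C, int N) {
  NumericVector dx((R_xlen_t)H * W * C * N);
  const double* pd = dout.begin();
  double* px = dx.begin();
  for (R_xlen_t i = 0; i < dout.size(); ++i) {
    px[argmax[i] - 1] += pd[i];
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}
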
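#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are column-major [H, W, C] arrays. im2col lowers a convolution
// to one matrix product: row q = io + jo*Ho enumerates output pixels in
// column-major order, column k = ki + kj*kh + c*kh*kw enumerates kernel taps.
// Out-of-image taps read zero (zero padding).

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix out(Ho * Wo, kh * kw * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kj * kh + c * kh * kw;
        double *dst = &out(0, col);
        for (int jo = 0; jo < Wo; ++jo) {
          const int jj = jo * stride - pad + kj;
          if (jj < 0 || jj >= W) {
            for (int io = 0; io < Ho; ++io) dst[io + jo * Ho] = 0.0;
            continue;
          }
          const double *src = px + jj * H + c * H * W;
          for (int io = 0; io < Ho; ++io) {
            const int ii = io * stride - pad + ki;
            dst[io + jo * Ho] = (ii >= 0 && ii < H) ? src[ii] : 0.0;
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add matrix columns back into an [H, W, C] array.
// Used for conv backward-data and transposed-conv forward.

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix m, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector x(H * W * C);  // zero-initialised
  double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kj * kh + c * kh * kw;
        const double *src = &m(0, col);
        for (int jo = 0; jo < Wo; ++jo) {
          const int jj = jo * stride - pad + kj;
          if (jj < 0 || jj >= W) continue;
          double *dst = px + jj * H + c * H * W;
          for (int io = 0; io < Ho; ++io) {
            const int ii = io * stride - pad + ki;
            if (ii >= 0 && ii < H) dst[ii] += src[io + jo * Ho];
          }
        }
      }
    }
  }
  return x;
}

// Max pooling with argmax bookkeeping (1-based linear indices into the input
// array; 0 where the window saw only padding, which cannot happen for the
// configurations used here).

// [[Rcpp::export]]
List maxpool_cpp(NumericVector x, int H, int W, int C,
                 int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out(Ho * Wo * C);
  IntegerVector arg(Ho * Wo * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        double best = R_NegInf;
        int best_idx = -1;
        for (int kj = 0; kj < k; ++kj) {
          const int jj = jo * stride - pad + kj;
          if (jj < 0 || jj >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int ii = io * stride - pad + ki;
            if (ii < 0 || ii >= H) continue;
            const int idx = ii + jj * H + c * H * W;
            if (px[idx] > best) { best = px[idx]; best_idx = idx; }
          }
        }
        const int q = io + jo * Ho + c * Ho * Wo;
        out[q] = (best_idx >= 0) ? best : 0.0;
        arg[q] = best_idx + 1;
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg,
                      _["Ho"] = Ho, _["Wo"] = Wo);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(NumericVector dout, IntegerVector argmax,
                                   int n_in) {
  NumericVector dx(n_in);
  for (int q = 0; q < dout.size(); ++q) {
    const int idx = argmax[q];
    if (idx > 0) dx[idx - 1] += dout[q];
  }
  return dx;
}
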
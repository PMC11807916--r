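#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Helpers for 3D convolutional layers (V-Net baseline).  Feature arrays use
// R layout dim = (D, H, W, C), column-major.  Convolutions are stride 1 with
// implicit zero padding (k-1)/2, realized as im2col + BLAS matrix products on
// the R side.  Column index = spatial voxel (column-major); row index runs
// kernel-depth fastest, then kernel-height, kernel-width, input channel.

// [[Rcpp::export(name = ".im2col3")]]
NumericMatrix im2col3(NumericVector x, IntegerVector dims, int k) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int pad = (k - 1) / 2;
  const R_xlen_t nvox = (R_xlen_t)D * H * W;
  NumericMatrix cols((R_xlen_t)k * k * k * C, nvox);
  double *out = REAL(cols);
  const double *in = REAL(x);
  const R_xlen_t nrow = (R_xlen_t)k * k * k * C;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        R_xlen_t col = (R_xlen_t)d + (R_xlen_t)D * (h + (R_xlen_t)H * w);
        double *dst = out + col * nrow;
        R_xlen_t r = 0;
        for (int c = 0; c < C; ++c) {
          const double *chan = in + (R_xlen_t)c * nvox;
          for (int kw = 0; kw < k; ++kw) {
            int ww = w + kw - pad;
            for (int kh = 0; kh < k; ++kh) {
              int hh = h + kh - pad;
              for (int kd = 0; kd < k; ++kd, ++r) {
                int dd = d + kd - pad;
                if (dd < 0 || dd >= D || hh < 0 || hh >= H || ww < 0 || ww >= W)
                  dst[r] = 0.0;
                else
                  dst[r] = chan[(R_xlen_t)dd + (R_xlen_t)D * (hh + (R_xlen_t)H * ww)];
              }
            }
          }
        }
      }
  return cols;
}

// Adjoint of im2col3: scatter-add column gradients back onto the input grid.
// [[Rcpp::export(name = ".col2im3")]]
NumericVector col2im3(NumericMatrix dcols, IntegerVector dims, int k) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int pad = (k - 1) / 2;
  const R_xlen_t nvox = (R_xlen_t)D * H * W;
  NumericVector dx((R_xlen_t)nvox * C);
  double *out = REAL(dx);
  const double *in = REAL(dcols);
  const R_xlen_t nrow = (R_xlen_t)k * k * k * C;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        R_xlen_t col = (R_xlen_t)d + (R_xlen_t)D * (h + (R_xlen_t)H * w);
        const double *src = in + col * nrow;
        R_xlen_t r = 0;
        for (int c = 0; c < C; ++c) {
          double *chan = out + (R_xlen_t)c * nvox;
          for (int kw = 0; kw < k; ++kw) {
            int ww = w + kw - pad;
            for (int kh = 0; kh < k; ++kh) {
              int hh = h + kh - pad;
              for (int kd = 0; kd < k; ++kd, ++r) {
                int dd = d + kd - pad;
                if (dd < 0 || dd >= D || hh < 0 || hh >= H || ww < 0 || ww >= W)
                  continue;
                chan[(R_xlen_t)dd + (R_xlen_t)D * (hh + (R_xlen_t)H * ww)] += src[r];
              }
            }
          }
        }
      }
  dx.attr("dim") = IntegerVector::create(D, H, W, C);
  return dx;
}

// [[Rcpp::export(name = ".maxpool3")]]
List maxpool3(NumericVector x, IntegerVector dims, int f) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  if (D % f || H % f || W % f) stop("dims not divisible by pooling factor");
  const int Do = D / f, Ho = H / f, Wo = W / f;
  const R_xlen_t nvox = (R_xlen_t)D * H * W;
  NumericVector y((R_xlen_t)Do * Ho * Wo * C);
  IntegerVector arg(y.size());
  const double *in = REAL(x);
  double *out = REAL(y);
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c) {
    const double *chan = in + (R_xlen_t)c * nvox;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d, ++o) {
          double best = R_NegInf;
          R_xlen_t bidx = 0;
          for (int kw = 0; kw < f; ++kw)
            for (int kh = 0; kh < f; ++kh)
              for (int kd = 0; kd < f; ++kd) {
                R_xlen_t idx = (R_xlen_t)(d*f+kd) +
                  (R_xlen_t)D * ((h*f+kh) + (R_xlen_t)H * (w*f+kw));
                if (chan[idx] > best) { best = chan[idx]; bidx = idx; }
              }
          out[o] = best;
          arg[o] = (int)((R_xlen_t)c * nvox + bidx); // 0-based into x
        }
  }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool3Backward")]]
NumericVector maxpool3Backward(NumericVector dy, IntegerVector argmax,
                               IntegerVector dims) {
  NumericVector dx((R_xlen_t)dims[0] * dims[1] * dims[2] * dims[3]);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[argmax[i]] += dy[i];
  dx.attr("dim") = dims;
  return dx;
}

// Nearest-neighbour upsampling by factor f, and its adjoint (block sum).
// [[Rcpp::export(name = ".upsample3")]]
NumericVector upsample3(NumericVector x, IntegerVector dims, int f) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Do = D * f, Ho = H * f, Wo = W * f;
  NumericVector y((R_xlen_t)Do * Ho * Wo * C);
  const double *in = REAL(x);
  double *out = REAL(y);
  const R_xlen_t nin = (R_xlen_t)D * H * W, nout = (R_xlen_t)Do * Ho * Wo;
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d)
          out[(R_xlen_t)c * nout + d + (R_xlen_t)Do * (h + (R_xlen_t)Ho * w)] =
            in[(R_xlen_t)c * nin + d/f + (R_xlen_t)D * (h/f + (R_xlen_t)H * (w/f))];
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  return y;
}

// [[Rcpp::export(name = ".upsample3Backward")]]
NumericVector upsample3Backward(NumericVector dy, IntegerVector outDims, int f) {
  const int Do = outDims[0], Ho = outDims[1], Wo = outDims[2], C = outDims[3];
  const int D = Do / f, H = Ho / f, W = Wo / f;
  NumericVector dx((R_xlen_t)D * H * W * C);
  const double *in = REAL(dy);
  double *out = REAL(dx);
  const R_xlen_t nin = (R_xlen_t)D * H * W, nout = (R_xlen_t)Do * Ho * Wo;
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d)
          out[(R_xlen_t)c * nin + d/f + (R_xlen_t)D * (h/f + (R_xlen_t)H * (w/f))] +=
            in[(R_xlen_t)c * nout + d + (R_xlen_t)Do * (h + (R_xlen_t)Ho * w)];
  dx.attr("dim") = IntegerVector::create(D, H, W, C);
  return dx;
}
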
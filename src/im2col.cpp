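#include <Rcpp.h>
using namespace Rcpp;

// Volumetric im2col / col2im for 3D convolution.
//
// A single sample is an R array with dim = (D, H, W, C), column-major.
// im2col3d unrolls every sliding k^3 window into one column of a
// (C * k^3) x (oD * oH * oW) matrix; the row order (kd fastest, then kh,
// kw, c) matches the column-major flattening of a weight array with
// dim = (k, k, k, C, outC), so convolution reduces to one GEMM done in R
// with the BLAS-backed %*%.

static inline int out_extent(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col3d(NumericVector x, IntegerVector dims, int k, int stride,
                       int pad) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int oD = out_extent(D, k, stride, pad);
  const int oH = out_extent(H, k, stride, pad);
  const int oW = out_extent(W, k, stride, pad);
  const int K = C * k * k * k;
  const R_xlen_t N = (R_xlen_t)oD * oH * oW;
  NumericMatrix out(K, N);
  const double* xp = REAL(x);
  double* op = REAL(out);

  for (R_xlen_t col = 0; col < N; ++col) {
    const int od = (int)(col % oD);
    const int oh = (int)((col / oD) % oH);
    const int ow = (int)(col / ((R_xlen_t)oD * oH));
    const int d0 = od * stride - pad;
    const int h0 = oh * stride - pad;
    const int w0 = ow * stride - pad;
    double* colp = op + col * K;
    int r = 0;
    for (int c = 0; c < C; ++c) {
      const R_xlen_t cbase = (R_xlen_t)D * H * W * c;
      for (int kw = 0; kw < k; ++kw) {
        const int w = w0 + kw;
        for (int kh = 0; kh < k; ++kh) {
          const int h = h0 + kh;
          for (int kd = 0; kd < k; ++kd, ++r) {
            const int d = d0 + kd;
            if (d >= 0 && d < D && h >= 0 && h < H && w >= 0 && w < W)
              colp[r] = xp[cbase + d + (R_xlen_t)D * (h + (R_xlen_t)H * w)];
            else
              colp[r] = 0.0;
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add adjoint of im2col3d: accumulates column gradients back onto
// the input grid. `cols` must be (C * k^3) x (oD * oH * oW).
// [[Rcpp::export]]
NumericVector col2im3d(NumericMatrix cols, IntegerVector dims, int k,
                       int stride, int pad) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int oD = out_extent(D, k, stride, pad);
  const int oH = out_extent(H, k, stride, pad);
  const int oW = out_extent(W, k, stride, pad);
  const int K = C * k * k * k;
  const R_xlen_t N = (R_xlen_t)oD * oH * oW;
  if (cols.nrow() != K || cols.ncol() != N)
    stop("col2im3d: column matrix does not match the stated geometry");
  NumericVector x((R_xlen_t)D * H * W * C);
  double* xp = REAL(x);
  const double* cp = REAL(cols);

  for (R_xlen_t col = 0; col < N; ++col) {
    const int od = (int)(col % oD);
    const int oh = (int)((col / oD) % oH);
    const int ow = (int)(col / ((R_xlen_t)oD * oH));
    const int d0 = od * stride - pad;
    const int h0 = oh * stride - pad;
    const int w0 = ow * stride - pad;
    const double* colp = cp + col * K;
    int r = 0;
    for (int c = 0; c < C; ++c) {
      const R_xlen_t cbase = (R_xlen_t)D * H * W * c;
      for (int kw = 0; kw < k; ++kw) {
        const int w = w0 + kw;
        for (int kh = 0; kh < k; ++kh) {
          const int h = h0 + kh;
          for (int kd = 0; kd < k; ++kd, ++r) {
            const int d = d0 + kd;
            if (d >= 0 && d < D && h >= 0 && h < H && w >= 0 && w < W)
              xp[cbase + d + (R_xlen_t)D * (h + (R_xlen_t)H * w)] += colp[r];
          }
        }
      }
    }
  }
  x.attr("dim") = dims;
  return x;
}
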
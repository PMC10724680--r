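#include <Rcpp.h>
using namespace Rcpp;

// 3D im2col / col2im for volumetric convolutions.
//
// Volumes are R arrays with dims (nx, ny, nz, C), column-major.
// The column matrix has one column per output location (x fastest, then y,
// then z) and one row per (kx, ky, kz, c) kernel entry, kx fastest —
// matching the column-major flattening of a (k, k, k, Cin, Cout) weight
// array, so conv forward is a single gemm against matrix(W, k^3*Cin, Cout).
// Loops run column-sequentially: each output location fills its column in
// one pass, with contiguous reads/writes along the kx axis.

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col3(NumericVector x, IntegerVector dims,
                          int k, int stride, int pad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  const int ox = out_size(nx, k, stride, pad);
  const int oy = out_size(ny, k, stride, pad);
  const int oz = out_size(nz, k, stride, pad);
  if (ox < 1 || oy < 1 || oz < 1)
    stop("kernel does not fit input (input %dx%dx%d, kernel %d, stride %d, pad %d)",
         nx, ny, nz, k, stride, pad);
  const int K = k * k * k * C;
  const R_xlen_t N = (R_xlen_t)ox * oy * oz;
  NumericMatrix col(K, N);
  const double* xp = x.begin();
  double* cp = col.begin();
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny, sc = (R_xlen_t)nx * ny * nz;

  R_xlen_t cidx = 0;
  for (int z = 0; z < oz; ++z) {
    const int z0 = z * stride - pad;
    for (int y = 0; y < oy; ++y) {
      const int y0 = y * stride - pad;
      for (int xo = 0; xo < ox; ++xo, ++cidx) {
        const int x0 = xo * stride - pad;
        double* dst = cp + cidx * K;
        for (int c = 0; c < C; ++c) {
          const double* xc = xp + sc * c;
          for (int kz = 0; kz < k; ++kz) {
            const int iz = z0 + kz;
            const bool zin = iz >= 0 && iz < nz;
            for (int ky = 0; ky < k; ++ky) {
              const int iy = y0 + ky;
              if (!zin || iy < 0 || iy >= ny) {
                for (int kx = 0; kx < k; ++kx) *dst++ = 0.0;
                continue;
              }
              const double* src = xc + sz * iz + sy * iy;
              for (int kx = 0; kx < k; ++kx) {
                const int ix = x0 + kx;
                *dst++ = (ix >= 0 && ix < nx) ? src[ix] : 0.0;
              }
            }
          }
        }
      }
    }
  }
  return col;
}

// Scatter-add a column matrix back onto a volume of dims (nx, ny, nz, C):
// the adjoint of cpp_im2col3, used for conv input-gradients and for the
// forward pass of stride-2 transposed convolutions.
// [[Rcpp::export]]
NumericVector cpp_col2im3(NumericMatrix col, IntegerVector dims,
                          int k, int stride, int pad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  const int ox = out_size(nx, k, stride, pad);
  const int oy = out_size(ny, k, stride, pad);
  const int oz = out_size(nz, k, stride, pad);
  const int K = k * k * k * C;
  const R_xlen_t N = (R_xlen_t)ox * oy * oz;
  if (col.nrow() != K || col.ncol() != N)
    stop("column matrix is %dx%td but expected %dx%td",
         col.nrow(), (ptrdiff_t)col.ncol(), K, (ptrdiff_t)N);
  NumericVector out((R_xlen_t)nx * ny * nz * C);
  out.attr("dim") = dims;
  double* op = out.begin();
  const double* cp = col.begin();
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny, sc = (R_xlen_t)nx * ny * nz;

  R_xlen_t cidx = 0;
  for (int z = 0; z < oz; ++z) {
    const int z0 = z * stride - pad;
    for (int y = 0; y < oy; ++y) {
      const int y0 = y * stride - pad;
      for (int xo = 0; xo < ox; ++xo, ++cidx) {
        const int x0 = xo * stride - pad;
        const double* src = cp + cidx * K;
        for (int c = 0; c < C; ++c) {
          double* oc = op + sc * c;
          for (int kz = 0; kz < k; ++kz) {
            const int iz = z0 + kz;
            const bool zin = iz >= 0 && iz < nz;
            for (int ky = 0; ky < k; ++ky) {
              const int iy = y0 + ky;
              if (!zin || iy < 0 || iy >= ny) { src += k; continue; }
              double* dst = oc + sz * iz + sy * iy;
              for (int kx = 0; kx < k; ++kx) {
                const int ix = x0 + kx;
                if (ix >= 0 && ix < nx) dst[ix] += src[kx];
              }
              src += k;
            }
          }
        }
      }
    }
  }
  return out;
}
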
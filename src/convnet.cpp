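// Strided 3D convolution via im2col + BLAS gemm (Armadillo). 2D convolution
// is the depth-1 special case handled by the R wrappers.
//
// Layouts (R column-major):
//   input   dim (X, Y, Z, Cin)
//   weights dim (k1, k2, k3, Cin, Cout)
//   output  dim (Xo, Yo, Zo, Cout),  Xo = (X + 2*p1 - k1)/stride + 1, etc.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int n, int k, int p, int s) {
  return (n + 2 * p - k) / s + 1;
}

// Fill the im2col matrix: rows = k1*k2*k3*Cin, cols = Xo*Yo*Zo.
static void im2col(const double *in, const int *nd, const int *kd,
                   const int *pd, int stride, int cin,
                   const int *od, arma::mat &cols) {
  const R_xlen_t sx = 1, sy = nd[0], sz = (R_xlen_t)nd[0] * nd[1],
                 sc = (R_xlen_t)nd[0] * nd[1] * nd[2];
  const int krows = kd[0] * kd[1] * kd[2];
  R_xlen_t col = 0;
  for (int oz = 0; oz < od[2]; ++oz) {
    const int z0 = oz * stride - pd[2];
    for (int oy = 0; oy < od[1]; ++oy) {
      const int y0 = oy * stride - pd[1];
      for (int ox = 0; ox < od[0]; ++ox, ++col) {
        const int x0 = ox * stride - pd[0];
        double *dst = cols.colptr(col);
        for (int c = 0; c < cin; ++c) {
          const double *base = in + c * sc;
          int row = 0;
          for (int kz = 0; kz < kd[2]; ++kz) {
            const int z = z0 + kz;
            for (int ky = 0; ky < kd[1]; ++ky) {
              const int y = y0 + ky;
              for (int kx = 0; kx < kd[0]; ++kx, ++row) {
                const int x = x0 + kx;
                dst[c * krows + row] =
                  (x >= 0 && x < nd[0] && y >= 0 && y < nd[1] &&
                   z >= 0 && z < nd[2])
                    ? base[x * sx + y * sy + z * sz]
                    : 0.0;
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add the im2col matrix back onto the input lattice (for grad-input).
static void col2im(const arma::mat &cols, const int *nd, const int *kd,
                   const int *pd, int stride, int cin,
                   const int *od, double *out) {
  const R_xlen_t sy = nd[0], sz = (R_xlen_t)nd[0] * nd[1],
                 sc = (R_xlen_t)nd[0] * nd[1] * nd[2];
  const int krows = kd[0] * kd[1] * kd[2];
  R_xlen_t col = 0;
  for (int oz = 0; oz < od[2]; ++oz) {
    const int z0 = oz * stride - pd[2];
    for (int oy = 0; oy < od[1]; ++oy) {
      const int y0 = oy * stride - pd[1];
      for (int ox = 0; ox < od[0]; ++ox, ++col) {
        const int x0 = ox * stride - pd[0];
        const double *src = cols.colptr(col);
        for (int c = 0; c < cin; ++c) {
          double *base = out + c * sc;
          int row = 0;
          for (int kz = 0; kz < kd[2]; ++kz) {
            const int z = z0 + kz;
            for (int ky = 0; ky < kd[1]; ++ky) {
              const int y = y0 + ky;
              for (int kx = 0; kx < kd[0]; ++kx, ++row) {
                const int x = x0 + kx;
                if (x >= 0 && x < nd[0] && y >= 0 && y < nd[1] &&
                    z >= 0 && z < nd[2])
                  base[x + y * sy + z * sz] += src[c * krows + row];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_fwd_cpp")]]
NumericVector conv3d_fwd_cpp(NumericVector input, NumericVector weights,
                             NumericVector bias, int stride,
                             IntegerVector pad) {
  IntegerVector di = input.attr("dim"), dw = weights.attr("dim");
  const int nd[3] = {di[0], di[1], di[2]};
  const int cin = di[3];
  const int kd[3] = {dw[0], dw[1], dw[2]};
  const int cout = dw[4];
  const int pd[3] = {pad[0], pad[1], pad[2]};
  const int od[3] = {out_dim(nd[0], kd[0], pd[0], stride),
                     out_dim(nd[1], kd[1], pd[1], stride),
                     out_dim(nd[2], kd[2], pd[2], stride)};
  const int krows = kd[0] * kd[1] * kd[2] * cin;
  const R_xlen_t ncols = (R_xlen_t)od[0] * od[1] * od[2];
  arma::mat cols(krows, ncols);
  im2col(input.begin(), nd, kd, pd, stride, cin, od, cols);
  arma::mat W(weights.begin(), krows, cout, false);  // (k^3*Cin) x Cout
  arma::mat out = W.t() * cols;                      // Cout x N
  for (int c = 0; c < cout; ++c) out.row(c) += bias[c];
  NumericVector res(ncols * cout);
  // reorder Cout x N -> (N, Cout) column blocks
  arma::mat resm(res.begin(), ncols, cout, false);
  resm = out.t();
  res.attr("dim") = IntegerVector::create(od[0], od[1], od[2], cout);
  return res;
}

// [[Rcpp::export(name = ".conv3d_bwd_cpp")]]
List conv3d_bwd_cpp(NumericVector gradout, NumericVector input,
                    NumericVector weights, int stride, IntegerVector pad,
                    bool need_gradin) {
  IntegerVector di = input.attr("dim"), dw = weights.attr("dim"),
                dg = gradout.attr("dim");
  const int nd[3] = {di[0], di[1], di[2]};
  const int cin = di[3];
  const int kd[3] = {dw[0], dw[1], dw[2]};
  const int cout = dw[4];
  const int pd[3] = {pad[0], pad[1], pad[2]};
  const int od[3] = {dg[0], dg[1], dg[2]};
  const int krows = kd[0] * kd[1] * kd[2] * cin;
  const R_xlen_t ncols = (R_xlen_t)od[0] * od[1] * od[2];

  arma::mat cols(krows, ncols);
  im2col(input.begin(), nd, kd, pd, stride, cin, od, cols);
  arma::mat G(gradout.begin(), ncols, cout, false);  // N x Cout

  NumericVector gW(weights.size());
  arma::mat gWm(gW.begin(), krows, cout, false);
  gWm = cols * G;                                    // krows x Cout
  gW.attr("dim") = dw;

  NumericVector gb(cout);
  arma::rowvec gbv = arma::sum(G, 0);
  for (int c = 0; c < cout; ++c) gb[c] = gbv[c];

  List out = List::create(_["grad_w"] = gW, _["grad_b"] = gb);
  if (need_gradin) {
    arma::mat W(weights.begin(), krows, cout, false);
    arma::mat gcols = W * G.t();                     // krows x N
    NumericVector gin(input.size());
    std::fill(gin.begin(), gin.end(), 0.0);
    col2im(gcols, nd, kd, pd, stride, cin, od, gin.begin());
    gin.attr("dim") = di;
    out["grad_in"] = gin;
  }
  return out;
}
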
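#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation of a 3D grid at continuous voxel coordinates
// (0-based; voxel centers at integer coordinates). Points outside
// [0, n-1] along any axis get value 0 and validity 0. Optionally returns
// the spatial gradient (per voxel unit) and an interpolated mask.
//
// vol:   numeric array, dim (nx, ny, nz), column-major
// mask:  same shape, or length 0 to skip mask interpolation
// px, py, pz: coordinates of the sample points
// [[Rcpp::export(name = ".trilinear_cpp")]]
List trilinear_cpp(NumericVector vol, NumericVector mask,
                   NumericVector px, NumericVector py, NumericVector pz,
                   bool grad = false) {
  IntegerVector d = vol.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t n = px.size();
  const bool has_mask = mask.size() > 0;
  NumericVector val(n), valid(n);
  NumericVector mval = has_mask ? NumericVector(n) : NumericVector(0);
  NumericVector gx, gy, gz;
  if (grad) { gx = NumericVector(n); gy = NumericVector(n); gz = NumericVector(n); }
  const double *v = vol.begin();
  const double *m = has_mask ? mask.begin() : nullptr;

  for (R_xlen_t p = 0; p < n; ++p) {
    const double x = px[p], y = py[p], z = pz[p];
    if (!(x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0)) {
      continue;  // zero fill, validity 0
    }
    valid[p] = 1.0;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0--;  // sample exactly on the far face
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    const double fx = x - i0, fy = y - j0, fz = z - k0;
    const int i1 = (nx == 1) ? i0 : i0 + 1;
    const int j1 = (ny == 1) ? j0 : j0 + 1;
    const int k1 = (nz == 1) ? k0 : k0 + 1;
    #define V(ii, jj, kk) v[(ii) + nx * ((jj) + (R_xlen_t)ny * (kk))]
    const double c000 = V(i0, j0, k0), c100 = V(i1, j0, k0);
    const double c010 = V(i0, j1, k0), c110 = V(i1, j1, k0);
    const double c001 = V(i0, j0, k1), c101 = V(i1, j0, k1);
    const double c011 = V(i0, j1, k1), c111 = V(i1, j1, k1);
    #undef V
    // (1-f)*a + f*b lerp form: exact at f = 0 and f = 1, so lattice points
    // (including the far faces) reproduce stored values bit for bit
    const double c00 = (1 - fx) * c000 + fx * c100;
    const double c10 = (1 - fx) * c010 + fx * c110;
    const double c01 = (1 - fx) * c001 + fx * c101;
    const double c11 = (1 - fx) * c011 + fx * c111;
    const double c0 = (1 - fy) * c00 + fy * c10;
    const double c1 = (1 - fy) * c01 + fy * c11;
    val[p] = (1 - fz) * c0 + fz * c1;
    if (grad) {
      // d/dfz
      gz[p] = c1 - c0;
      // d/dfy at fixed fz
      gy[p] = (c10 - c00) + fz * ((c11 - c01) - (c10 - c00));
      // d/dfx
      const double d00 = c100 - c000, d10 = c110 - c010;
      const double d01 = c101 - c001, d11 = c111 - c011;
      const double d0 = d00 + fy * (d10 - d00);
      const double d1 = d01 + fy * (d11 - d01);
      gx[p] = d0 + fz * (d1 - d0);
    }
    if (has_mask) {
      #define M(ii, jj, kk) m[(ii) + nx * ((jj) + (R_xlen_t)ny * (kk))]
      const double m00 = (1 - fx) * M(i0, j0, k0) + fx * M(i1, j0, k0);
      const double m10 = (1 - fx) * M(i0, j1, k0) + fx * M(i1, j1, k0);
      const double m01 = (1 - fx) * M(i0, j0, k1) + fx * M(i1, j0, k1);
      const double m11 = (1 - fx) * M(i0, j1, k1) + fx * M(i1, j1, k1);
      #undef M
      const double ma = (1 - fy) * m00 + fy * m10;
      const double mb = (1 - fy) * m01 + fy * m11;
      mval[p] = (1 - fz) * ma + fz * mb;
    }
  }
  List out = List::create(_["value"] = val, _["valid"] = valid);
  if (has_mask) out["mask"] = mval;
  if (grad) { out["gx"] = gx; out["gy"] = gy; out["gz"] = gz; }
  return out;
}

// Separable Gaussian smoothing of a 3D array with per-axis sigma in voxels.
// Kernel truncated at 3 sigma; edges renormalized (kernel mass inside).
// [[Rcpp::export(name = ".gauss_smooth3_cpp")]]
NumericVector gauss_smooth3_cpp(NumericVector vol, NumericVector sigma) {
  IntegerVector d = vol.attr("dim");
  const int n[3] = {d[0], d[1], d[2]};
  std::vector<double> buf(vol.begin(), vol.end());
  std::vector<double> tmp(buf.size());
  const R_xlen_t stride[3] = {1, (R_xlen_t)n[0], (R_xlen_t)n[0] * n[1]};

  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0) continue;
    const int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * r + 1);
    for (int i = -r; i <= r; ++i) k[i + r] = std::exp(-0.5 * i * i / (s * s));
    const int na = n[ax];
    const R_xlen_t sa = stride[ax];
    const R_xlen_t total = (R_xlen_t)n[0] * n[1] * n[2];
    // iterate over all lines along axis ax
    for (R_xlen_t base = 0; base < total; ++base) {
      // compute the coordinate along ax of this element
      R_xlen_t idx = base;
      int coord[3];
      coord[0] = idx % n[0]; idx /= n[0];
      coord[1] = idx % n[1]; idx /= n[1];
      coord[2] = (int)idx;
      const int a = coord[ax];
      double acc = 0.0, wsum = 0.0;
      const int lo = std::max(-a, -r), hi = std::min(na - 1 - a, r);
      for (int off = lo; off <= hi; ++off) {
        const double w = k[off + r];
        acc += w * buf[base + (R_xlen_t)off * sa];
        wsum += w;
      }
      tmp[base] = acc / wsum;
    }
    buf.swap(tmp);
  }
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = d;
  return out;
}

// Sum of values over k x k windows centered at every pixel of a 2D matrix,
// windows clipped at the image boundary (outside pixels contribute 0).
// Uses a summed-area table; k must be odd.
// [[Rcpp::export(name = ".box_sum_cpp")]]
NumericMatrix box_sum_cpp(NumericMatrix x, int k) {
  const int nr = x.nrow(), nc = x.ncol(), r = k / 2;
  // summed-area table S with a zero row/col border: S(i,j) = sum x[0..i-1,0..j-1]
  std::vector<double> S((nr + 1) * (size_t)(nc + 1), 0.0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      S[(i + 1) + (size_t)(nr + 1) * (j + 1)] =
        x(i, j) + S[i + (size_t)(nr + 1) * (j + 1)] +
        S[(i + 1) + (size_t)(nr + 1) * j] - S[i + (size_t)(nr + 1) * j];
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const int j0 = std::max(0, j - r), j1 = std::min(nc - 1, j + r);
    for (int i = 0; i < nr; ++i) {
      const int i0 = std::max(0, i - r), i1 = std::min(nr - 1, i + r);
      out(i, j) = S[(i1 + 1) + (size_t)(nr + 1) * (j1 + 1)] -
                  S[i0 + (size_t)(nr + 1) * (j1 + 1)] -
                  S[(i1 + 1) + (size_t)(nr + 1) * j0] +
                  S[i0 + (size_t)(nr + 1) * j0];
    }
  }
  return out;
}
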
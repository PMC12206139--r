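// Separable convolution along one array axis (reflect boundary) and
// closed-form eigenvalues of the voxelwise symmetric 3x3 Hessian, sorted by
// absolute value. Used by the Frangi-type tubularness filter.
#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// axis: 0 = z (fastest-varying), 1 = y, 2 = x; kernel length must be odd
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector vol, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int kl = kernel.size(), kr = kl / 2;
  NumericVector out(vol.size());
  const int n = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  // stride along the convolved axis and sizes of the two other loops
  R_xlen_t stride;
  if (axis == 0) stride = 1;
  else if (axis == 1) stride = nz;
  else stride = (R_xlen_t)nz * ny;
  const R_xlen_t total = (R_xlen_t)nz * ny * nx;
  const R_xlen_t nlines = total / n;
  std::vector<double> line(n);
  for (R_xlen_t l = 0; l < nlines; ++l) {
    // base index of this line
    R_xlen_t base;
    if (axis == 0) base = l * nz;
    else if (axis == 1) {
      const R_xlen_t z = l % nz, x = l / nz;
      base = z + (R_xlen_t)nz * ny * x;
    } else {
      base = l;  // l enumerates (z, y) pairs directly
    }
    for (int i = 0; i < n; ++i) line[i] = vol[base + stride * i];
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int k = -kr; k <= kr; ++k) {
        int j = i + k;
        while (j < 0 || j >= n) {              // reflect (repeatedly, in case
          if (j < 0) j = -j - 1;               //  the kernel spans the axis)
          if (j >= n) j = 2 * n - j - 1;
        }
        acc += line[j] * kernel[k + kr];
      }
      out[base + stride * i] = acc;
    }
  }
  return out;
}

// Eigenvalues of symmetric 3x3 matrices (trigonometric method), returned
// sorted by increasing absolute value (|l1| <= |l2| <= |l3|).
// [[Rcpp::export]]
List cpp_sym_eigs(NumericVector hzz, NumericVector hyy, NumericVector hxx,
                  NumericVector hzy, NumericVector hzx, NumericVector hyx) {
  const R_xlen_t n = hzz.size();
  NumericVector l1(n), l2(n), l3(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double a = hzz[i], b = hyy[i], c = hxx[i];
    const double d = hzy[i], e = hzx[i], f = hyx[i];
    double eig[3];
    const double p1 = d * d + e * e + f * f;
    if (p1 == 0.0) {
      eig[0] = a; eig[1] = b; eig[2] = c;
    } else {
      const double q = (a + b + c) / 3.0;
      const double p2 = (a - q) * (a - q) + (b - q) * (b - q) +
                        (c - q) * (c - q) + 2.0 * p1;
      const double p = std::sqrt(p2 / 6.0);
      // B = (A - q I) / p; r = det(B) / 2 clamped to [-1, 1]
      const double b11 = (a - q) / p, b22 = (b - q) / p, b33 = (c - q) / p;
      const double b12 = d / p, b13 = e / p, b23 = f / p;
      double r = (b11 * (b22 * b33 - b23 * b23) -
                  b12 * (b12 * b33 - b23 * b13) +
                  b13 * (b12 * b23 - b22 * b13)) / 2.0;
      r = std::max(-1.0, std::min(1.0, r));
      const double phi = std::acos(r) / 3.0;
      eig[0] = q + 2.0 * p * std::cos(phi);
      eig[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      eig[1] = 3.0 * q - eig[0] - eig[2];
    }
    std::sort(eig, eig + 3,
              [](double u, double v) { return std::fabs(u) < std::fabs(v); });
    l1[i] = eig[0]; l2[i] = eig[1]; l3[i] = eig[2];
  }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3);
}
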
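#include <Rcpp.h>
using namespace Rcpp;

// Eigenvalues of a symmetric 3x3 matrix, trigonometric closed form
// (Smith 1961). Returned sorted by increasing absolute value, ties broken
// by signed value ascending.
static inline void sym3_eigenvalues(double a11, double a12, double a13,
                                    double a22, double a23, double a33,
                                    double ev[3]) {
  const double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  const double q = (a11 + a22 + a33) / 3.0;
  const double b11 = a11 - q, b22 = a22 - q, b33 = a33 - q;
  const double p2 = b11 * b11 + b22 * b22 + b33 * b33 + 2.0 * p1;
  if (p2 <= 0.0) { ev[0] = ev[1] = ev[2] = q; return; }
  const double p = std::sqrt(p2 / 6.0);
  // det(B)/2 with B = (A - qI)/p
  const double c11 = b11 / p, c12 = a12 / p, c13 = a13 / p;
  const double c22 = b22 / p, c23 = a23 / p, c33 = b33 / p;
  double r = 0.5 * (c11 * (c22 * c33 - c23 * c23)
                    - c12 * (c12 * c33 - c23 * c13)
                    + c13 * (c12 * c23 - c22 * c13));
  if (r < -1.0) r = -1.0; else if (r > 1.0) r = 1.0;
  const double phi = std::acos(r) / 3.0;
  const double e1 = q + 2.0 * p * std::cos(phi);
  const double e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  const double e2 = 3.0 * q - e1 - e3;
  ev[0] = e1; ev[1] = e2; ev[2] = e3;
  // sort by |.| ascending, ties by signed value ascending
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2 - i; ++j) {
      const double aj = std::fabs(ev[j]), ak = std::fabs(ev[j + 1]);
      if (aj > ak || (aj == ak && ev[j] > ev[j + 1]))
        std::swap(ev[j], ev[j + 1]);
    }
}

// Per-voxel eigenvalues of a symmetric tensor field given by its six
// unique component volumes (xx, xy, xz, yy, yz, zz). Returns a list of
// three volumes ordered by increasing |eigenvalue|.
// [[Rcpp::export(name = ".tensor_eigenvalues_cpp")]]
List tensor_eigenvalues_cpp(NumericVector xx, NumericVector xy, NumericVector xz,
                            NumericVector yy, NumericVector yz, NumericVector zz) {
  const R_xlen_t n = xx.size();
  NumericVector e1(n), e2(n), e3(n);
  e1.attr("dim") = xx.attr("dim");
  e2.attr("dim") = xx.attr("dim");
  e3.attr("dim") = xx.attr("dim");
  double ev[3];
  for (R_xlen_t i = 0; i < n; ++i) {
    sym3_eigenvalues(xx[i], xy[i], xz[i], yy[i], yz[i], zz[i], ev);
    e1[i] = ev[0]; e2[i] = ev[1]; e3[i] = ev[2];
  }
  return List::create(e1, e2, e3);
}
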
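#include <Rcpp.h>
using namespace Rcpp;

// Separable 3D convolution along one axis with replicate padding.
// True convolution: out[i] = sum_t in[i - t] * k[t + f], t = -f..f.
// axis: 0 = x (dim 1), 1 = y (dim 2), 2 = z (dim 3).
// [[Rcpp::export(name = ".conv_axis_cpp")]]
NumericVector conv_axis_cpp(NumericVector vol, NumericVector kernel, int axis) {
  IntegerVector dim = vol.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int klen = kernel.size();
  const int f = (klen - 1) / 2;
  NumericVector out(vol.size());
  out.attr("dim") = dim;
  const double *in = vol.begin();
  const double *k = kernel.begin();
  double *o = out.begin();

  const int n[3] = {nx, ny, nz};
  const int nax = n[axis];
  // strides in linear index space (column-major)
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const R_xlen_t stride = (axis == 0) ? sx : (axis == 1) ? sy : sz;

  // iterate over all lines along `axis`
  const int nu = (axis == 0) ? ny : nx;
  const int nv = (axis == 2) ? ny : nz;
  const R_xlen_t su = (axis == 0) ? sy : sx;
  const R_xlen_t sv = (axis == 2) ? sy : sz;

  std::vector<double> line(nax);
  for (int v = 0; v < nv; ++v) {
    for (int u = 0; u < nu; ++u) {
      const R_xlen_t base = u * su + v * sv;
      for (int i = 0; i < nax; ++i) line[i] = in[base + i * stride];
      for (int i = 0; i < nax; ++i) {
        double acc = 0.0;
        for (int t = -f; t <= f; ++t) {
          int j = i - t;
          if (j < 0) j = 0; else if (j >= nax) j = nax - 1;  // replicate
          acc += line[j] * k[t + f];
        }
        o[base + i * stride] = acc;
      }
    }
  }
  return out;
}

// Mean over an arbitrary voxel-offset neighbourhood, replicate padding.
// offsets: m x 3 integer matrix of (dx, dy, dz).
// [[Rcpp::export(name = ".offset_mean_cpp")]]
NumericVector offset_mean_cpp(NumericVector vol, IntegerMatrix offsets) {
  IntegerVector dim = vol.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int m = offsets.nrow();
  NumericVector out(vol.size());
  out.attr("dim") = dim;
  const double *in = vol.begin();
  double *o = out.begin();
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        for (int t = 0; t < m; ++t) {
          int tx = x + offsets(t, 0), ty = y + offsets(t, 1), tz = z + offsets(t, 2);
          tx = tx < 0 ? 0 : (tx >= nx ? nx - 1 : tx);
          ty = ty < 0 ? 0 : (ty >= ny ? ny - 1 : ty);
          tz = tz < 0 ? 0 : (tz >= nz ? nz - 1 : tz);
          acc += in[tx + (R_xlen_t)nx * (ty + (R_xlen_t)ny * tz)];
        }
        o[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = acc / m;
      }
    }
  }
  return out;
}

// Local Shannon entropy (base 2) of 8-bit intensities in a cubic window
// of half-size f, replicate padding.
// [[Rcpp::export(name = ".local_entropy_cpp")]]
NumericVector local_entropy_cpp(IntegerVector vol, int f) {
  IntegerVector dim = vol.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(vol.size());
  out.attr("dim") = dim;
  const int *in = vol.begin();
  double *o = out.begin();
  const int side = 2 * f + 1;
  const double nU = (double)side * side * side;
  std::vector<int> hist(256);
  const double log2e = 1.0 / std::log(2.0);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        std::fill(hist.begin(), hist.end(), 0);
        for (int dz = -f; dz <= f; ++dz) {
          int tz = z + dz; tz = tz < 0 ? 0 : (tz >= nz ? nz - 1 : tz);
          for (int dy = -f; dy <= f; ++dy) {
            int ty = y + dy; ty = ty < 0 ? 0 : (ty >= ny ? ny - 1 : ty);
            for (int dx = -f; dx <= f; ++dx) {
              int tx = x + dx; tx = tx < 0 ? 0 : (tx >= nx ? nx - 1 : tx);
              ++hist[in[tx + (R_xlen_t)nx * (ty + (R_xlen_t)ny * tz)]];
            }
          }
        }
        double h = 0.0;
        for (int l = 0; l < 256; ++l) {
          if (hist[l] > 0) {
            double p = hist[l] / nU;
            h -= p * std::log(p) * log2e;
          }
        }
        o[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = h;
      }
    }
  }
  return out;
}
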
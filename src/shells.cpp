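#include <Rcpp.h>
using namespace Rcpp;

// Exact anisotropic Euclidean distance (nm, between voxel centers) from a
// set of seed voxels, evaluated on the seed bounding box padded by the
// voxel reach of dmax and clipped to the volume. Distances beyond dmax are
// reported as +Inf. Seeds are 1-based voxel coordinates (n x 3).
// Returns list(dist = 3D array over the padded box, lo = 1-based box origin).
// [[Rcpp::export(name = ".seed_distance_cpp")]]
List seed_distance_cpp(IntegerMatrix seeds, IntegerVector dims,
                       NumericVector voxel_size, double dmax) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double vx = voxel_size[0], vy = voxel_size[1], vz = voxel_size[2];
  const int mx = (int)std::floor(dmax / vx), my = (int)std::floor(dmax / vy),
            mz = (int)std::floor(dmax / vz);
  const int ns = seeds.nrow();
  if (ns == 0) stop("no seed voxels");

  int lo[3] = {INT_MAX, INT_MAX, INT_MAX}, hi[3] = {INT_MIN, INT_MIN, INT_MIN};
  for (int i = 0; i < ns; ++i)
    for (int d = 0; d < 3; ++d) {
      if (seeds(i, d) < lo[d]) lo[d] = seeds(i, d);
      if (seeds(i, d) > hi[d]) hi[d] = seeds(i, d);
    }
  const int m[3] = {mx, my, mz}, n[3] = {nx, ny, nz};
  for (int d = 0; d < 3; ++d) {
    lo[d] = std::max(1, lo[d] - m[d]);
    hi[d] = std::min(n[d], hi[d] + m[d]);
  }
  const int bx = hi[0] - lo[0] + 1, by = hi[1] - lo[1] + 1, bz = hi[2] - lo[2] + 1;

  // precompute all offsets within dmax
  std::vector<int> ox, oy, oz;
  std::vector<double> od;
  const double dmax2 = dmax * dmax;
  for (int dz = -mz; dz <= mz; ++dz)
    for (int dy = -my; dy <= my; ++dy)
      for (int dx = -mx; dx <= mx; ++dx) {
        const double d2 = dx * vx * dx * vx + dy * vy * dy * vy + dz * vz * dz * vz;
        if (d2 <= dmax2) {
          ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
          od.push_back(std::sqrt(d2));
        }
      }

  NumericVector dist((R_xlen_t)bx * by * bz, R_PosInf);
  dist.attr("dim") = IntegerVector::create(bx, by, bz);
  double *dd = dist.begin();
  const size_t noff = ox.size();
  for (int i = 0; i < ns; ++i) {
    const int sx = seeds(i, 0), sy = seeds(i, 1), sz = seeds(i, 2);
    for (size_t t = 0; t < noff; ++t) {
      const int tx = sx + ox[t], ty = sy + oy[t], tz = sz + oz[t];
      if (tx < lo[0] || tx > hi[0] || ty < lo[1] || ty > hi[1] ||
          tz < lo[2] || tz > hi[2]) continue;
      const R_xlen_t idx = (tx - lo[0]) +
        (R_xlen_t)bx * ((ty - lo[1]) + (R_xlen_t)by * (tz - lo[2]));
      if (od[t] < dd[idx]) dd[idx] = od[t];
    }
  }
  return List::create(_["dist"] = dist,
                      _["lo"] = IntegerVector::create(lo[0], lo[1], lo[2]));
}
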
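#include <Rcpp.h>
using namespace Rcpp;

// Count of integer lattice points inside (or on) the convex hull of a 3D
// point set, via an incremental convex hull. Points with affine rank < 3
// (collinear/coplanar clouds) fall back to the number of distinct input
// points; this matches the convention that degenerate clouds contribute
// their own voxels and nothing else.

struct Face { int a, b, c; double nx, ny, nz, off; };

static inline void face_plane(const std::vector<double> &px,
                              const std::vector<double> &py,
                              const std::vector<double> &pz,
                              Face &f) {
  const double ux = px[f.b] - px[f.a], uy = py[f.b] - py[f.a], uz = pz[f.b] - pz[f.a];
  const double vx = px[f.c] - px[f.a], vy = py[f.c] - py[f.a], vz = pz[f.c] - pz[f.a];
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.off = f.nx * px[f.a] + f.ny * py[f.a] + f.nz * pz[f.a];
}

// [[Rcpp::export(name = ".hull_lattice_count_cpp")]]
double hull_lattice_count_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n == 0) return 0.0;
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) { px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2); }

  auto distinct_count = [&]() {
    std::set<std::array<long long, 3>> s;
    for (int i = 0; i < n; ++i)
      s.insert({(long long)llround(px[i]), (long long)llround(py[i]),
                (long long)llround(pz[i])});
    return (double)s.size();
  };

  // initial simplex: most separated points in x, then line, then plane
  double span = 0.0;
  for (int d = 0; d < 3; ++d) {
    double mn = R_PosInf, mx = R_NegInf;
    for (int i = 0; i < n; ++i) {
      const double v = d == 0 ? px[i] : (d == 1 ? py[i] : pz[i]);
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    span = std::max(span, mx - mn);
  }
  const double eps = 1e-9 * std::max(1.0, span);

  int i0 = 0, i1 = -1;
  double best = -1.0;
  for (int i = 1; i < n; ++i) {
    const double dx = px[i] - px[i0], dy = py[i] - py[i0], dz = pz[i] - pz[i0];
    const double d = dx * dx + dy * dy + dz * dz;
    if (d > best) { best = d; i1 = i; }
  }
  if (i1 < 0 || best <= eps * eps) return distinct_count();
  int i2 = -1; best = -1.0;
  const double ax = px[i1] - px[i0], ay = py[i1] - py[i0], az = pz[i1] - pz[i0];
  for (int i = 0; i < n; ++i) {
    const double bx = px[i] - px[i0], by = py[i] - py[i0], bz = pz[i] - pz[i0];
    const double cx = ay * bz - az * by, cy = az * bx - ax * bz, cz = ax * by - ay * bx;
    const double d = cx * cx + cy * cy + cz * cz;
    if (d > best) { best = d; i2 = i; }
  }
  if (best <= eps * eps) return distinct_count();
  Face f0 = {i0, i1, i2, 0, 0, 0, 0};
  face_plane(px, py, pz, f0);
  int i3 = -1; best = -1.0;
  for (int i = 0; i < n; ++i) {
    const double d = std::fabs(f0.nx * px[i] + f0.ny * py[i] + f0.nz * pz[i] - f0.off);
    if (d > best) { best = d; i3 = i; }
  }
  if (best <= eps) return distinct_count();

  // interior reference point
  const double gx = (px[i0] + px[i1] + px[i2] + px[i3]) / 4.0;
  const double gy = (py[i0] + py[i1] + py[i2] + py[i3]) / 4.0;
  const double gz = (pz[i0] + pz[i1] + pz[i2] + pz[i3]) / 4.0;

  std::vector<Face> faces;
  int tet[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  for (int t = 0; t < 4; ++t) {
    Face f = {tet[t][0], tet[t][1], tet[t][2], 0, 0, 0, 0};
    face_plane(px, py, pz, f);
    if (f.nx * gx + f.ny * gy + f.nz * gz - f.off > 0) {  // orient outward
      std::swap(f.b, f.c);
      face_plane(px, py, pz, f);
    }
    faces.push_back(f);
  }

  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    std::vector<int> visible;
    for (size_t t = 0; t < faces.size(); ++t) {
      const Face &f = faces[t];
      const double nn = std::sqrt(f.nx * f.nx + f.ny * f.ny + f.nz * f.nz);
      if (f.nx * px[i] + f.ny * py[i] + f.nz * pz[i] - f.off > eps * nn)
        visible.push_back((int)t);
    }
    if (visible.empty()) continue;
    // horizon edges: edges used by exactly one visible face
    std::map<std::pair<int, int>, int> edge_count;
    for (int t : visible) {
      const Face &f = faces[t];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int k = 0; k < 3; ++k) {
        std::pair<int, int> key(std::min(e[k][0], e[k][1]), std::max(e[k][0], e[k][1]));
        edge_count[key]++;
      }
    }
    std::vector<Face> kept;
    std::set<int> vis(visible.begin(), visible.end());
    for (size_t t = 0; t < faces.size(); ++t)
      if (!vis.count((int)t)) kept.push_back(faces[t]);
    for (auto &ec : edge_count) {
      if (ec.second != 1) continue;
      Face f = {ec.first.first, ec.first.second, i, 0, 0, 0, 0};
      face_plane(px, py, pz, f);
      const double nn = std::sqrt(f.nx * f.nx + f.ny * f.ny + f.nz * f.nz);
      if (nn <= eps) continue;  // degenerate sliver
      if (f.nx * gx + f.ny * gy + f.nz * gz - f.off > 0) {
        std::swap(f.b, f.c);
        face_plane(px, py, pz, f);
      }
      kept.push_back(f);
    }
    faces.swap(kept);
  }

  // count lattice points in the bounding box inside all face half-spaces
  long long lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    double mn = R_PosInf, mx = R_NegInf;
    for (int i = 0; i < n; ++i) {
      const double v = d == 0 ? px[i] : (d == 1 ? py[i] : pz[i]);
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    lo[d] = (long long)std::ceil(mn - 0.5);
    hi[d] = (long long)std::floor(mx + 0.5);
  }
  // normalize planes once
  std::vector<std::array<double, 4>> planes;
  for (const Face &f : faces) {
    const double nn = std::sqrt(f.nx * f.nx + f.ny * f.ny + f.nz * f.nz);
    if (nn <= eps) continue;
    planes.push_back({f.nx / nn, f.ny / nn, f.nz / nn, f.off / nn});
  }
  double count = 0.0;
  for (long long z = lo[2]; z <= hi[2]; ++z)
    for (long long y = lo[1]; y <= hi[1]; ++y)
      for (long long x = lo[0]; x <= hi[0]; ++x) {
        bool inside = true;
        for (const auto &pl : planes) {
          if (pl[0] * x + pl[1] * y + pl[2] * z - pl[3] > eps) { inside = false; break; }
        }
        if (inside) count += 1.0;
      }
  return count;
}
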
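// Voxel-grid geometry kernels: iso-surface area by marching tetrahedra,
// 3D connected-component labelling, binary morphology, separable Gaussian
// smoothing. All grids are column-major R arrays indexed [x, y, z].
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double field_at(const double* f, int nx, int ny, int nz,
                              int i, int j, int k, double outside) {
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return outside;
  return f[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
}

struct Vec3 { double x, y, z; };

static inline Vec3 lerp_edge(const Vec3& a, const Vec3& b, double va, double vb,
                             double level) {
  double t = (level - va) / (vb - va);
  Vec3 p;
  p.x = a.x + t * (b.x - a.x);
  p.y = a.y + t * (b.y - a.y);
  p.z = a.z + t * (b.z - a.z);
  return p;
}

static inline double tri_area(const Vec3& p, const Vec3& q, const Vec3& r) {
  double ux = q.x - p.x, uy = q.y - p.y, uz = q.z - p.z;
  double vx = r.x - p.x, vy = r.y - p.y, vz = r.z - p.z;
  double cx = uy * vz - uz * vy;
  double cy = uz * vx - ux * vz;
  double cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// Area contributed by one tetrahedron of the iso-surface at `level`.
static double tet_area(const Vec3 p[4], const double v[4], double level) {
  bool in[4];
  int nin = 0;
  for (int i = 0; i < 4; ++i) { in[i] = v[i] >= level; if (in[i]) ++nin; }
  if (nin == 0 || nin == 4) return 0.0;
  int a[3], b[3];  // indices of minority / majority sets
  if (nin == 1 || nin == 3) {
    bool minority_in = (nin == 1);
    int m = -1, o = 0;
    int others[3];
    for (int i = 0; i < 4; ++i) {
      if (in[i] == minority_in) m = i; else others[o++] = i;
    }
    Vec3 q0 = lerp_edge(p[m], p[others[0]], v[m], v[others[0]], level);
    Vec3 q1 = lerp_edge(p[m], p[others[1]], v[m], v[others[1]], level);
    Vec3 q2 = lerp_edge(p[m], p[others[2]], v[m], v[others[2]], level);
    return tri_area(q0, q1, q2);
  }
  // nin == 2: quad cut, split into two triangles
  int na = 0, nb = 0;
  for (int i = 0; i < 4; ++i) { if (in[i]) a[na++] = i; else b[nb++] = i; }
  Vec3 q00 = lerp_edge(p[a[0]], p[b[0]], v[a[0]], v[b[0]], level);
  Vec3 q01 = lerp_edge(p[a[0]], p[b[1]], v[a[0]], v[b[1]], level);
  Vec3 q10 = lerp_edge(p[a[1]], p[b[0]], v[a[1]], v[b[0]], level);
  Vec3 q11 = lerp_edge(p[a[1]], p[b[1]], v[a[1]], v[b[1]], level);
  return tri_area(q00, q01, q11) + tri_area(q00, q11, q10);
}

// 6 tetrahedra sharing the main diagonal 0-7 (corner bits: 1=x, 2=y, 4=z)
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};

// [[Rcpp::export(name = ".mt_surface_area")]]
double mt_surface_area(NumericVector field, IntegerVector dim,
                       double level, NumericVector spacing,
                       double outside = 0.0) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double* f = field.begin();
  double area = 0.0;
  // iterate cells including a one-voxel border of `outside`
  for (int k = -1; k < nz; ++k)
    for (int j = -1; j < ny; ++j)
      for (int i = -1; i < nx; ++i) {
        double v[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          v[c] = field_at(f, nx, ny, nz, ci, cj, ck, outside);
          (v[c] >= level ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        Vec3 p[8];
        for (int c = 0; c < 8; ++c) {
          p[c].x = (i + (c & 1)) * sx;
          p[c].y = (j + ((c >> 1) & 1)) * sy;
          p[c].z = (k + ((c >> 2) & 1)) * sz;
        }
        for (int t = 0; t < 6; ++t) {
          Vec3 tp[4]; double tv[4];
          for (int c = 0; c < 4; ++c) { tp[c] = p[TETS[t][c]]; tv[c] = v[TETS[t][c]]; }
          area += tet_area(tp, tv, level);
        }
      }
  return area;
}

// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      size_t u = stack.back(); stack.pop_back();
      int i = u % nx, j = (u / nx) % ny, k = u / ((size_t)nx * ny);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        size_t w = (size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * kk);
        if (mask[w] && lab[w] == 0) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}

// Chamfer-free exact box dilation via sliding window per axis.
static void axis_maxmin(std::vector<unsigned char>& a, int nx, int ny, int nz,
                        int axis, int r, bool do_max) {
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  std::vector<unsigned char> line(len);
  int outer1 = (axis == 0) ? ny : nx;
  int outer2 = (axis == 2) ? ny : nz;
  for (int b = 0; b < outer2; ++b)
    for (int a2 = 0; a2 < outer1; ++a2) {
      for (int t = 0; t < len; ++t) {
        int i, j, k;
        if (axis == 0) { i = t; j = a2; k = b; }
        else if (axis == 1) { i = a2; j = t; k = b; }
        else { i = a2; j = b; k = t; }
        line[t] = a[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
      }
      for (int t = 0; t < len; ++t) {
        unsigned char vv = line[t];
        for (int d = 1; d <= r; ++d) {
          if (t - d >= 0) vv = do_max ? std::max(vv, line[t - d]) : std::min(vv, line[t - d]);
          else if (!do_max) vv = 0;
          if (t + d < len) vv = do_max ? std::max(vv, line[t + d]) : std::min(vv, line[t + d]);
          else if (!do_max) vv = 0;
        }
        int i, j, k;
        if (axis == 0) { i = t; j = a2; k = b; }
        else if (axis == 1) { i = a2; j = t; k = b; }
        else { i = a2; j = b; k = t; }
        a[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)] = vv;
      }
    }
}

// [[Rcpp::export(name = ".binary_morph")]]
LogicalVector binary_morph(LogicalVector mask, IntegerVector dim, int radius,
                           std::string op) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<unsigned char> a(n);
  for (size_t s = 0; s < n; ++s) a[s] = mask[s] ? 1 : 0;
  auto dil = [&]() { for (int ax = 0; ax < 3; ++ax) axis_maxmin(a, nx, ny, nz, ax, radius, true); };
  auto ero = [&]() { for (int ax = 0; ax < 3; ++ax) axis_maxmin(a, nx, ny, nz, ax, radius, false); };
  if (op == "dilate") dil();
  else if (op == "erode") ero();
  else if (op == "close") { dil(); ero(); }
  else if (op == "open") { ero(); dil(); }
  else stop("unknown morphology op");
  LogicalVector out(n);
  for (size_t s = 0; s < n; ++s) out[s] = a[s] != 0;
  return out;
}

// Fill interior holes: background voxels not reachable from the border.
// [[Rcpp::export(name = ".fill_holes")]]
LogicalVector fill_holes(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<unsigned char> reach(n, 0);
  std::vector<size_t> stack;
  auto push_if = [&](int i, int j, int k) {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return;
    size_t s = (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
    if (!reach[s] && !mask[s]) { reach[s] = 1; stack.push_back(s); }
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 || k == nz - 1)
          push_if(i, j, k);
  while (!stack.empty()) {
    size_t u = stack.back(); stack.pop_back();
    int i = u % nx, j = (u / nx) % ny, k = u / ((size_t)nx * ny);
    push_if(i - 1, j, k); push_if(i + 1, j, k);
    push_if(i, j - 1, k); push_if(i, j + 1, k);
    push_if(i, j, k - 1); push_if(i, j, k + 1);
  }
  LogicalVector out(n);
  for (size_t s = 0; s < n; ++s) out[s] = mask[s] || !reach[s];
  return out;
}

// Separable Gaussian smoothing, reflective boundaries; sigma in voxels per axis.
// [[Rcpp::export(name = ".gauss_smooth")]]
NumericVector gauss_smooth(NumericVector vol, IntegerVector dim,
                           NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  int dims[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> w(2 * r + 1);
    double tot = 0;
    for (int d = -r; d <= r; ++d) { w[d + r] = std::exp(-0.5 * d * d / (s * s)); tot += w[d + r]; }
    for (auto& x : w) x /= tot;
    int len = dims[axis];
    for (size_t u = 0; u < n; ++u) {
      int i = u % nx, j = (u / nx) % ny, k = u / ((size_t)nx * ny);
      int t = (axis == 0) ? i : (axis == 1) ? j : k;
      double acc = 0;
      for (int d = -r; d <= r; ++d) {
        int tt = t + d;
        if (tt < 0) tt = -tt - 1;
        if (tt >= len) tt = 2 * len - tt - 1;
        size_t v;
        if (axis == 0) v = (size_t)tt + (size_t)nx * ((size_t)j + (size_t)ny * k);
        else if (axis == 1) v = (size_t)i + (size_t)nx * ((size_t)tt + (size_t)ny * k);
        else v = (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * tt);
        acc += w[d + r] * a[v];
      }
      b[u] = acc;
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable, with per-axis physical spacing. Input: 1 where feature, 0 elsewhere.
// Returns squared distance to the nearest feature voxel (physical units).
static void dt1d(std::vector<double>& f, std::vector<double>& d, double step) {
  int n = f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) / (2.0 * s2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (q - v[k]) * step;
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  const double INF = 1e30;
  std::vector<double> a(n);
  for (size_t s = 0; s < n; ++s) a[s] = mask[s] ? 0.0 : INF;
  int dims[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    int len = dims[axis];
    std::vector<double> line(len), dl(len);
    int o1 = (axis == 0) ? ny : nx;
    int o2 = (axis == 2) ? ny : nz;
    for (int b = 0; b < o2; ++b)
      for (int a2 = 0; a2 < o1; ++a2) {
        for (int t = 0; t < len; ++t) {
          int i, j, k;
          if (axis == 0) { i = t; j = a2; k = b; }
          else if (axis == 1) { i = a2; j = t; k = b; }
          else { i = a2; j = b; k = t; }
          line[t] = a[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
        }
        dt1d(line, dl, spacing[axis]);
        for (int t = 0; t < len; ++t) {
          int i, j, k;
          if (axis == 0) { i = t; j = a2; k = b; }
          else if (axis == 1) { i = a2; j = t; k = b; }
          else { i = a2; j = b; k = t; }
          a[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)] = dl[t];
        }
      }
  }
  return NumericVector(a.begin(), a.end());
}

// Staircase-corrected iso-surface area: marching-tetrahedra triangles of the
// binary mask at level 0.5, each triangle's area weighted by |cos| of the
// angle between its facet normal and the normal of a smoothed guide field
// (trilinear-interpolated gradient). Exact for axis-aligned flat faces and
// removes the lattice staircase inflation on curved surfaces.
static void tet_tris(const Vec3 p[4], const double v[4], double level,
                     std::vector<Vec3>& tris) {
  bool in[4]; int nin = 0;
  for (int i = 0; i < 4; ++i) { in[i] = v[i] >= level; if (in[i]) ++nin; }
  if (nin == 0 || nin == 4) return;
  if (nin == 1 || nin == 3) {
    bool minority_in = (nin == 1);
    int m = -1, o = 0; int others[3];
    for (int i = 0; i < 4; ++i) { if (in[i] == minority_in) m = i; else others[o++] = i; }
    tris.push_back(lerp_edge(p[m], p[others[0]], v[m], v[others[0]], level));
    tris.push_back(lerp_edge(p[m], p[others[1]], v[m], v[others[1]], level));
    tris.push_back(lerp_edge(p[m], p[others[2]], v[m], v[others[2]], level));
    return;
  }
  int a[2], b[2]; int na = 0, nb = 0;
  for (int i = 0; i < 4; ++i) { if (in[i]) a[na++] = i; else b[nb++] = i; }
  Vec3 q00 = lerp_edge(p[a[0]], p[b[0]], v[a[0]], v[b[0]], level);
  Vec3 q01 = lerp_edge(p[a[0]], p[b[1]], v[a[0]], v[b[1]], level);
  Vec3 q10 = lerp_edge(p[a[1]], p[b[0]], v[a[1]], v[b[0]], level);
  Vec3 q11 = lerp_edge(p[a[1]], p[b[1]], v[a[1]], v[b[1]], level);
  tris.push_back(q00); tris.push_back(q01); tris.push_back(q11);
  tris.push_back(q00); tris.push_back(q11); tris.push_back(q10);
}

// [[Rcpp::export(name = ".mt_area_corrected")]]
double mt_area_corrected(NumericVector field, IntegerVector dim,
                         double level, NumericVector spacing,
                         NumericVector guide, double outside = 0.0) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double* f = field.begin();
  const double* g = guide.begin();
  // guide gradient (physical units) at voxel (i,j,k), central differences
  auto guide_at = [&](int i, int j, int k) -> double {
    if (i < 0) i = 0; if (j < 0) j = 0; if (k < 0) k = 0;
    if (i >= nx) i = nx - 1; if (j >= ny) j = ny - 1; if (k >= nz) k = nz - 1;
    return g[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
  };
  auto grad_at = [&](double x, double y, double z, Vec3& out) {
    // nearest-voxel gradient at physical point (voxel coords = phys/spacing)
    int i = (int)std::lround(x / sx), j = (int)std::lround(y / sy),
        k = (int)std::lround(z / sz);
    out.x = (guide_at(i + 1, j, k) - guide_at(i - 1, j, k)) / (2 * sx);
    out.y = (guide_at(i, j + 1, k) - guide_at(i, j - 1, k)) / (2 * sy);
    out.z = (guide_at(i, j, k + 1) - guide_at(i, j, k - 1)) / (2 * sz);
  };
  double area = 0.0;
  std::vector<Vec3> tris;
  for (int k = -1; k < nz; ++k)
    for (int j = -1; j < ny; ++j)
      for (int i = -1; i < nx; ++i) {
        double v[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          v[c] = field_at(f, nx, ny, nz, ci, cj, ck, outside);
          (v[c] >= level ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        Vec3 p[8];
        for (int c = 0; c < 8; ++c) {
          p[c].x = (i + (c & 1)) * sx;
          p[c].y = (j + ((c >> 1) & 1)) * sy;
          p[c].z = (k + ((c >> 2) & 1)) * sz;
        }
        tris.clear();
        for (int t = 0; t < 6; ++t) {
          Vec3 tp[4]; double tv[4];
          for (int c = 0; c < 4; ++c) { tp[c] = p[TETS[t][c]]; tv[c] = v[TETS[t][c]]; }
          tet_tris(tp, tv, level, tris);
        }
        for (size_t t = 0; t + 2 < tris.size() + 1; t += 3) {
          const Vec3 &pa = tris[t], &pb = tris[t + 1], &pc = tris[t + 2];
          double ux = pb.x - pa.x, uy = pb.y - pa.y, uz = pb.z - pa.z;
          double vx = pc.x - pa.x, vy = pc.y - pa.y, vz = pc.z - pa.z;
          double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz,
                 cz = ux * vy - uy * vx;
          double a2 = std::sqrt(cx * cx + cy * cy + cz * cz);
          if (a2 <= 0) continue;
          Vec3 n;
          grad_at((pa.x + pb.x + pc.x) / 3, (pa.y + pb.y + pc.y) / 3,
                  (pa.z + pb.z + pc.z) / 3, n);
          double gn = std::sqrt(n.x * n.x + n.y * n.y + n.z * n.z);
          double w = 1.0;
          if (gn > 1e-9)
            w = std::fabs(cx * n.x + cy * n.y + cz * n.z) / (a2 * gn);
          area += 0.5 * a2 * w;
        }
      }
  return area;
}
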
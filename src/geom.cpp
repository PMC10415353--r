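// Mesh geometry kernels: signed-distance sampling on a regular grid,
// iso-surface extraction by marching tetrahedra, and point-to-mesh distance
// with a uniform-grid acceleration structure. Distances and coordinates in mm.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};
inline Vec3 v3(double x, double y, double z) { return {x, y, z}; }
inline Vec3 operator-(const Vec3 &a, const Vec3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 operator+(const Vec3 &a, const Vec3 &b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 operator*(double s, const Vec3 &a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}

// Closest point on triangle (a,b,c) to p. Ericson, Real-Time Collision Detection.
Vec3 closest_on_triangle(const Vec3 &p, const Vec3 &a, const Vec3 &b, const Vec3 &c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + v * ab;
  }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return a + w * ac;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + w * (c - b);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + v * ab + w * ac;
}

inline double sq(double x) { return x * x; }

struct TriMesh {
  std::vector<Vec3> V;
  std::vector<int> F; // 3 per face, 0-based

  void load(const NumericMatrix &Vm, const IntegerMatrix &Fm) {
    int nv = Vm.nrow(), nf = Fm.nrow();
    V.resize(nv);
    for (int i = 0; i < nv; ++i) V[i] = v3(Vm(i, 0), Vm(i, 1), Vm(i, 2));
    F.resize(3 * nf);
    for (int i = 0; i < nf; ++i) {
      F[3 * i] = Fm(i, 0) - 1;
      F[3 * i + 1] = Fm(i, 1) - 1;
      F[3 * i + 2] = Fm(i, 2) - 1;
    }
  }
  int nfaces() const { return (int)F.size() / 3; }
  Vec3 tv(int f, int k) const { return V[F[3 * f + k]]; }
};

// Uniform grid over triangle bounding boxes.
struct TriGrid {
  Vec3 lo;
  double cell;
  int nx, ny, nz;
  std::vector<std::vector<int>> bins;

  void build(const TriMesh &m, double cell_size) {
    Vec3 hi = m.V[0];
    lo = m.V[0];
    for (const auto &p : m.V) {
      lo.x = std::min(lo.x, p.x); lo.y = std::min(lo.y, p.y); lo.z = std::min(lo.z, p.z);
      hi.x = std::max(hi.x, p.x); hi.y = std::max(hi.y, p.y); hi.z = std::max(hi.z, p.z);
    }
    cell = cell_size;
    nx = std::max(1, (int)std::floor((hi.x - lo.x) / cell) + 1);
    ny = std::max(1, (int)std::floor((hi.y - lo.y) / cell) + 1);
    nz = std::max(1, (int)std::floor((hi.z - lo.z) / cell) + 1);
    bins.assign((size_t)nx * ny * nz, {});
    for (int f = 0; f < m.nfaces(); ++f) {
      Vec3 a = m.tv(f, 0), b = m.tv(f, 1), c = m.tv(f, 2);
      double x0 = std::min({a.x, b.x, c.x}), x1 = std::max({a.x, b.x, c.x});
      double y0 = std::min({a.y, b.y, c.y}), y1 = std::max({a.y, b.y, c.y});
      double z0 = std::min({a.z, b.z, c.z}), z1 = std::max({a.z, b.z, c.z});
      int i0 = clampi((int)std::floor((x0 - lo.x) / cell), nx);
      int i1 = clampi((int)std::floor((x1 - lo.x) / cell), nx);
      int j0 = clampi((int)std::floor((y0 - lo.y) / cell), ny);
      int j1 = clampi((int)std::floor((y1 - lo.y) / cell), ny);
      int k0 = clampi((int)std::floor((z0 - lo.z) / cell), nz);
      int k1 = clampi((int)std::floor((z1 - lo.z) / cell), nz);
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i)
            bins[idx(i, j, k)].push_back(f);
    }
  }
  static int clampi(int v, int n) { return std::max(0, std::min(n - 1, v)); }
  size_t idx(int i, int j, int k) const { return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k); }

  // Unsigned distance from p to mesh, expanding-ring search; returns value
  // possibly capped at `cap` (if no triangle within cap, returns cap).
  double distance(const TriMesh &m, const Vec3 &p, double cap) const {
    int ci = clampi((int)std::floor((p.x - lo.x) / cell), nx);
    int cj = clampi((int)std::floor((p.y - lo.y) / cell), ny);
    int ck = clampi((int)std::floor((p.z - lo.z) / cell), nz);
    double best = cap;
    int max_ring = std::max({nx, ny, nz});
    for (int r = 0; r <= max_ring; ++r) {
      // once best distance is smaller than the guaranteed clearance of ring r, stop
      if ((double)(r - 1) * cell > best) break;
      bool any = false;
      int i0 = ci - r, i1 = ci + r, j0 = cj - r, j1 = cj + r, k0 = ck - r, k1 = ck + r;
      for (int k = k0; k <= k1; ++k) {
        if (k < 0 || k >= nz) continue;
        for (int j = j0; j <= j1; ++j) {
          if (j < 0 || j >= ny) continue;
          for (int i = i0; i <= i1; ++i) {
            if (i < 0 || i >= nx) continue;
            // shell only
            if (r > 0 && i != i0 && i != i1 && j != j0 && j != j1 && k != k0 && k != k1) continue;
            any = true;
            for (int f : bins[idx(i, j, k)]) {
              Vec3 q = closest_on_triangle(p, m.tv(f, 0), m.tv(f, 1), m.tv(f, 2));
              double d2 = sq(p.x - q.x) + sq(p.y - q.y) + sq(p.z - q.z);
              double d = std::sqrt(d2);
              if (d < best) best = d;
            }
          }
        }
      }
      if (!any && r > max_ring) break;
    }
    return best;
  }
};

// Parity (inside/outside) by x-directed scanline rays through grid rows.
// Triangles binned on (y,z); small deterministic jitter avoids edge hits.
void scanline_inside(const TriMesh &m, const Vec3 &origin, double pitch,
                     int nx, int ny, int nz, std::vector<uint8_t> &inside) {
  inside.assign((size_t)nx * ny * nz, 0);
  // bin triangles by their (y,z) bounding box on the row lattice
  std::vector<std::vector<int>> rowbins((size_t)ny * nz);
  for (int f = 0; f < m.nfaces(); ++f) {
    Vec3 a = m.tv(f, 0), b = m.tv(f, 1), c = m.tv(f, 2);
    double y0 = std::min({a.y, b.y, c.y}), y1 = std::max({a.y, b.y, c.y});
    double z0 = std::min({a.z, b.z, c.z}), z1 = std::max({a.z, b.z, c.z});
    int j0 = std::max(0, (int)std::ceil((y0 - origin.y) / pitch - 0.51));
    int j1 = std::min(ny - 1, (int)std::floor((y1 - origin.y) / pitch + 0.51));
    int k0 = std::max(0, (int)std::ceil((z0 - origin.z) / pitch - 0.51));
    int k1 = std::min(nz - 1, (int)std::floor((z1 - origin.z) / pitch + 0.51));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        rowbins[(size_t)j + (size_t)ny * k].push_back(f);
  }
  const double jy = 0.5e-4 * pitch, jz = 0.5e-4 * pitch * 0.7;
  std::vector<double> xs;
  for (int k = 0; k < nz; ++k) {
    double z0 = origin.z + k * pitch + jz;
    for (int j = 0; j < ny; ++j) {
      double y0 = origin.y + j * pitch + jy;
      const auto &cand = rowbins[(size_t)j + (size_t)ny * k];
      if (cand.empty()) continue;
      xs.clear();
      for (int f : cand) {
        Vec3 a = m.tv(f, 0), b = m.tv(f, 1), c = m.tv(f, 2);
        // 2D point-in-triangle in (y,z)
        double d = (b.y - a.y) * (c.z - a.z) - (c.y - a.y) * (b.z - a.z);
        if (std::fabs(d) < 1e-300) continue; // degenerate in projection
        double w1 = ((y0 - a.y) * (c.z - a.z) - (c.y - a.y) * (z0 - a.z)) / d;
        double w2 = ((b.y - a.y) * (z0 - a.z) - (y0 - a.y) * (b.z - a.z)) / d;
        if (w1 < 0.0 || w2 < 0.0 || w1 + w2 > 1.0) continue;
        double x = a.x + w1 * (b.x - a.x) + w2 * (c.x - a.x);
        xs.push_back(x);
      }
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      size_t rowoff = (size_t)nx * ((size_t)j + (size_t)ny * k);
      size_t c = 0;
      for (int i = 0; i < nx; ++i) {
        double x = origin.x + i * pitch;
        while (c < xs.size() && xs[c] < x) ++c;
        // odd number of crossings behind (< x) means inside
        if (c & 1) inside[rowoff + i] = 1;
      }
    }
  }
}

} // namespace

// Signed distance of each grid node to the mesh surface; negative inside.
// Magnitude exact within `band`, clamped to +/-band outside it.
// [[Rcpp::export]]
NumericVector cpp_signed_distance_grid(NumericMatrix V, IntegerMatrix F,
                                       NumericVector origin, IntegerVector dims,
                                       double pitch, double band) {
  TriMesh m;
  m.load(V, F);
  int nx = dims[0], ny = dims[1], nz = dims[2];
  Vec3 o = v3(origin[0], origin[1], origin[2]);

  std::vector<uint8_t> inside;
  scanline_inside(m, o, pitch, nx, ny, nz, inside);

  TriGrid grid;
  grid.build(m, std::max(band, pitch));

  NumericVector out((size_t)nx * ny * nz);
  // compute exact distances only where a node could be within `band` of the
  // surface: any node whose 6-neighbourhood parity differs, plus a dilation
  // by the band radius in nodes.
  int brad = (int)std::ceil(band / pitch) + 1;
  std::vector<uint8_t> near((size_t)nx * ny * nz, 0);
  auto at = [&](int i, int j, int k) -> uint8_t {
    return inside[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        uint8_t c = at(i, j, k);
        bool boundary = false;
        if (i + 1 < nx && at(i + 1, j, k) != c) boundary = true;
        else if (i > 0 && at(i - 1, j, k) != c) boundary = true;
        else if (j + 1 < ny && at(i, j + 1, k) != c) boundary = true;
        else if (j > 0 && at(i, j - 1, k) != c) boundary = true;
        else if (k + 1 < nz && at(i, j, k + 1) != c) boundary = true;
        else if (k > 0 && at(i, j, k - 1) != c) boundary = true;
        else if (c && (i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 || k == nz - 1))
          boundary = true; // inside node on the grid boundary
        if (boundary) {
          for (int dk = -brad; dk <= brad; ++dk) {
            int kk = k + dk; if (kk < 0 || kk >= nz) continue;
            for (int dj = -brad; dj <= brad; ++dj) {
              int jj = j + dj; if (jj < 0 || jj >= ny) continue;
              for (int di = -brad; di <= brad; ++di) {
                int ii = i + di; if (ii < 0 || ii >= nx) continue;
                near[(size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * kk)] = 1;
              }
            }
          }
        }
      }

  size_t n = (size_t)nx * ny * nz;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
        double d;
        if (near[id]) {
          Vec3 p = v3(o.x + i * pitch, o.y + j * pitch, o.z + k * pitch);
          d = grid.distance(m, p, band);
        } else {
          d = band;
        }
        out[id] = inside[id] ? -d : d;
      }
  (void)n;
  return out;
}

// Marching tetrahedra over a scalar grid; extracts the 0-level surface.
// Values < 0 are interior. Returns list(vertices, triangles) with triangles
// oriented so normals point from the interior to the exterior (outward).
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector values, NumericVector origin,
                       IntegerVector dims, double pitch) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  Vec3 o = v3(origin[0], origin[1], origin[2]);
  auto gid = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * k);
  };
  auto val = [&](int64_t g) -> double {
    double v = values[(size_t)g];
    // exact zeros (nodes on the surface) are pushed outside so no tet corner
    // sits on the iso-level, keeping the triangulation non-degenerate
    return (v > -1e-12 && v < 1e-12) ? 1e-12 : v;
  };
  auto pos = [&](int64_t g) -> Vec3 {
    int i = (int)(g % nx);
    int j = (int)((g / nx) % ny);
    int k = (int)(g / ((int64_t)nx * ny));
    return v3(o.x + i * pitch, o.y + j * pitch, o.z + k * pitch);
  };

  std::unordered_map<uint64_t, int> edge_vert;
  std::vector<Vec3> verts;
  std::vector<int> tris;

  auto edge_vertex = [&](int64_t ga, int64_t gb) -> int {
    if (ga > gb) std::swap(ga, gb);
    // collision-free key: grids here are far below 2^32 nodes
    uint64_t key = ((uint64_t)ga << 32) | (uint64_t)(gb & 0xffffffff);
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double va = val(ga), vb = val(gb);
    double t = va / (va - vb);
    if (!(t >= 0.0 && t <= 1.0)) t = 0.5;
    Vec3 pa = pos(ga), pb = pos(gb);
    Vec3 p = pa + t * (pb - pa);
    int id = (int)verts.size();
    verts.push_back(p);
    edge_vert.emplace(key, id);
    return id;
  };

  // 6 tetrahedra per cube sharing the main diagonal c0-c6 (consistent across cubes)
  static const int tet_corner[6][4] = {
    {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
    {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};

  auto emit_tri = [&](int a, int b, int c, const Vec3 &out_dir) {
    Vec3 n = cross(verts[b] - verts[a], verts[c] - verts[a]);
    if (dot(n, out_dir) >= 0) {
      tris.push_back(a); tris.push_back(b); tris.push_back(c);
    } else {
      tris.push_back(a); tris.push_back(c); tris.push_back(b);
    }
  };

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        int64_t c[8] = {
          gid(i, j, k),         gid(i + 1, j, k),
          gid(i + 1, j + 1, k), gid(i, j + 1, k),
          gid(i, j, k + 1),     gid(i + 1, j, k + 1),
          gid(i + 1, j + 1, k + 1), gid(i, j + 1, k + 1)};
        // quick reject: all same sign
        bool any_neg = false, any_pos = false;
        for (int q = 0; q < 8; ++q) (val(c[q]) < 0.0 ? any_neg : any_pos) = true;
        if (!any_neg || !any_pos) continue;
        for (int t = 0; t < 6; ++t) {
          int64_t g[4];
          double v[4];
          bool neg[4];
          int nneg = 0;
          for (int q = 0; q < 4; ++q) {
            g[q] = c[tet_corner[t][q]];
            v[q] = val(g[q]);
            neg[q] = v[q] < 0.0;
            if (neg[q]) ++nneg;
          }
          if (nneg == 0 || nneg == 4) continue;
          // outward reference: gradient of the linear interpolant over the
          // tet (the iso-triangle is exactly perpendicular to it, so the
          // sign test is robust even for sliver triangles)
          Vec3 p0 = pos(g[0]);
          Vec3 e1 = pos(g[1]) - p0, e2 = pos(g[2]) - p0, e3 = pos(g[3]) - p0;
          double b1 = v[1] - v[0], b2 = v[2] - v[0], b3 = v[3] - v[0];
          double det = dot(e1, cross(e2, e3));
          Vec3 out_dir = (1.0 / det) * (b1 * cross(e2, e3) + b2 * cross(e3, e1) + b3 * cross(e1, e2));
          if (nneg == 1 || nneg == 3) {
            int a = -1; // the lone corner
            for (int q = 0; q < 4; ++q)
              if (neg[q] == (nneg == 1)) a = q;
            int others[3], m = 0;
            for (int q = 0; q < 4; ++q) if (q != a) others[m++] = q;
            int va_ = edge_vertex(g[a], g[others[0]]);
            int vb_ = edge_vertex(g[a], g[others[1]]);
            int vc_ = edge_vertex(g[a], g[others[2]]);
            emit_tri(va_, vb_, vc_, out_dir);
          } else {
            // two negative: quad between the 4 crossing edges
            int ni[2], pi[2], mn = 0, mp = 0;
            for (int q = 0; q < 4; ++q) (neg[q] ? ni[mn++] : pi[mp++]) = q;
            int q00 = edge_vertex(g[ni[0]], g[pi[0]]);
            int q01 = edge_vertex(g[ni[0]], g[pi[1]]);
            int q10 = edge_vertex(g[ni[1]], g[pi[0]]);
            int q11 = edge_vertex(g[ni[1]], g[pi[1]]);
            emit_tri(q00, q01, q11, out_dir);
            emit_tri(q00, q11, q10, out_dir);
          }
        }
      }

  int nv = (int)verts.size(), nf = (int)tris.size() / 3;
  NumericMatrix Vm(nv, 3);
  for (int i = 0; i < nv; ++i) {
    Vm(i, 0) = verts[i].x; Vm(i, 1) = verts[i].y; Vm(i, 2) = verts[i].z;
  }
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nf; ++i) {
    Fm(i, 0) = tris[3 * i] + 1; Fm(i, 1) = tris[3 * i + 1] + 1; Fm(i, 2) = tris[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = Vm, _["triangles"] = Fm);
}

// Unsigned distance from each query point to the mesh surface.
// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  TriMesh m;
  m.load(V, F);
  // pick a cell size of the order of the mean triangle edge
  double lensum = 0;
  int nf = m.nfaces();
  for (int f = 0; f < std::min(nf, 2000); ++f) {
    Vec3 a = m.tv(f, 0), b = m.tv(f, 1);
    lensum += std::sqrt(sq(a.x - b.x) + sq(a.y - b.y) + sq(a.z - b.z));
  }
  double cell = std::max(1e-6, 2.0 * lensum / std::min(nf, 2000));
  TriGrid grid;
  grid.build(m, cell);
  int np = P.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    Vec3 p = v3(P(i, 0), P(i, 1), P(i, 2));
    out[i] = grid.distance(m, p, std::numeric_limits<double>::infinity());
  }
  return out;
}

// Intersect a triangle mesh with a plane; returns a list of closed loops
// (k x 3 matrices), chained through shared triangle edges.
// [[Rcpp::export]]
List cpp_slice_mesh(NumericMatrix V, IntegerMatrix F,
                    NumericVector origin, NumericVector normal) {
  int nv = V.nrow(), nf = F.nrow();
  std::vector<double> d(nv);
  for (int i = 0; i < nv; ++i) {
    double s = (V(i, 0) - origin[0]) * normal[0] + (V(i, 1) - origin[1]) * normal[1] +
               (V(i, 2) - origin[2]) * normal[2];
    d[i] = (s > -1e-12 && s < 1e-12) ? 1e-12 : s;
  }
  // crossing segments keyed by the (sorted) vertex pair of each cut edge
  std::unordered_map<uint64_t, int> edge_id;
  std::vector<Vec3> pts;
  std::vector<int> seg_a, seg_b;
  auto cut = [&](int a, int b) -> int {
    int lo = std::min(a, b), hi = std::max(a, b);
    uint64_t key = ((uint64_t)lo << 32) | (uint64_t)hi;
    auto it = edge_id.find(key);
    if (it != edge_id.end()) return it->second;
    double t = d[a] / (d[a] - d[b]);
    Vec3 p = v3(V(a, 0) + t * (V(b, 0) - V(a, 0)),
                V(a, 1) + t * (V(b, 1) - V(a, 1)),
                V(a, 2) + t * (V(b, 2) - V(a, 2)));
    int id = (int)pts.size();
    pts.push_back(p);
    edge_id.emplace(key, id);
    return id;
  };
  for (int f = 0; f < nf; ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    bool pa = d[a] > 0, pb = d[b] > 0, pc = d[c] > 0;
    if (pa == pb && pb == pc) continue;
    int lone, o1, o2;
    if (pa != pb && pa != pc) { lone = a; o1 = b; o2 = c; }
    else if (pb != pa && pb != pc) { lone = b; o1 = a; o2 = c; }
    else { lone = c; o1 = a; o2 = b; }
    seg_a.push_back(cut(lone, o1));
    seg_b.push_back(cut(lone, o2));
  }
  int ns = (int)seg_a.size();
  // adjacency: each cut point belongs to exactly two segments on a
  // watertight mesh
  std::vector<std::vector<int>> at(pts.size());
  for (int i = 0; i < ns; ++i) {
    at[seg_a[i]].push_back(i);
    at[seg_b[i]].push_back(i);
  }
  std::vector<bool> used(ns, false);
  List out;
  for (int start = 0; start < ns; ++start) {
    if (used[start]) continue;
    used[start] = true;
    std::vector<int> chain;
    chain.push_back(seg_a[start]);
    chain.push_back(seg_b[start]);
    while (true) {
      int tail = chain.back();
      int nxt = -1;
      for (int si : at[tail]) if (!used[si]) { nxt = si; break; }
      if (nxt < 0) break;
      used[nxt] = true;
      int nk = (seg_a[nxt] == tail) ? seg_b[nxt] : seg_a[nxt];
      if (nk == chain.front()) break;
      chain.push_back(nk);
    }
    if (chain.size() < 3) continue;
    NumericMatrix loop((int)chain.size(), 3);
    for (size_t i = 0; i < chain.size(); ++i) {
      loop((int)i, 0) = pts[chain[i]].x;
      loop((int)i, 1) = pts[chain[i]].y;
      loop((int)i, 2) = pts[chain[i]].z;
    }
    out.push_back(loop);
  }
  return out;
}

// Closest surface point on the mesh for each query point (brute force over
// triangles; used for a handful of points at a time).
// [[Rcpp::export]]
NumericMatrix cpp_closest_point_on_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  TriMesh m;
  m.load(V, F);
  int np = P.nrow(), nf = m.nfaces();
  NumericMatrix out(np, 3);
  for (int i = 0; i < np; ++i) {
    Vec3 p = v3(P(i, 0), P(i, 1), P(i, 2));
    double best = std::numeric_limits<double>::infinity();
    Vec3 bq = p;
    for (int f = 0; f < nf; ++f) {
      Vec3 q = closest_on_triangle(p, m.tv(f, 0), m.tv(f, 1), m.tv(f, 2));
      double d2 = sq(p.x - q.x) + sq(p.y - q.y) + sq(p.z - q.z);
      if (d2 < best) { best = d2; bq = q; }
    }
    out(i, 0) = bq.x; out(i, 1) = bq.y; out(i, 2) = bq.z;
  }
  return out;
}

// Are points inside a watertight mesh? Parity along +x rays (brute force over
// candidate triangles found via a (y,z) interval test). Used for containment
// properties on moderate meshes.
// [[Rcpp::export]]
LogicalVector cpp_points_inside(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  TriMesh m;
  m.load(V, F);
  int np = P.nrow(), nf = m.nfaces();
  LogicalVector out(np);
  for (int i = 0; i < np; ++i) {
    double px = P(i, 0), py = P(i, 1) + 1.23456e-7, pz = P(i, 2) + 0.98765e-7;
    int crossings = 0;
    for (int f = 0; f < nf; ++f) {
      Vec3 a = m.tv(f, 0), b = m.tv(f, 1), c = m.tv(f, 2);
      double d = (b.y - a.y) * (c.z - a.z) - (c.y - a.y) * (b.z - a.z);
      if (std::fabs(d) < 1e-300) continue;
      double w1 = ((py - a.y) * (c.z - a.z) - (c.y - a.y) * (pz - a.z)) / d;
      double w2 = ((b.y - a.y) * (pz - a.z) - (py - a.y) * (b.z - a.z)) / d;
      if (w1 < 0.0 || w2 < 0.0 || w1 + w2 > 1.0) continue;
      double x = a.x + w1 * (b.x - a.x) + w2 * (c.x - a.x);
      if (x > px) ++crossings;
    }
    out[i] = (crossings & 1) != 0;
  }
  return out;
}
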
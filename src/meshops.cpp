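// Low-level triangle-mesh kernels: isosurface extraction (marching
// tetrahedra on a Freudenthal-split lattice), closest point on a mesh with a
// uniform-grid accelerator, ray-triangle casting, and a directed-edge audit
// used by the watertightness validator.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
};
inline V3 operator-(const V3& a, const V3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline V3 operator+(const V3& a, const V3& b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline V3 operator*(double s, const V3& a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(const V3& a, const V3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm2(const V3& a) { return dot(a, a); }

} // namespace

// ---------------------------------------------------------------------------
// Marching tetrahedra
// ---------------------------------------------------------------------------

// Freudenthal 6-tet split of each lattice cube (all tets share the main
// diagonal 0-7, so shared faces between neighbouring cubes are triangulated
// identically and the extracted surface is watertight). Corner bit order:
// bit0 = +x, bit1 = +y, bit2 = +z.
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

// [[Rcpp::export(name = ".cpp_marching_tets")]]
List marching_tets(NumericVector values, int nx, int ny, int nz,
                   NumericVector origin, NumericVector spacing) {
  if ((R_xlen_t)nx * ny * nz != values.size())
    stop("values length does not match grid dims");
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const double* val = REAL(values);

  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> verts;   // x,y,z triples
  std::vector<int> faces;      // 1-based vertex ids, triples

  // corner gid and position helpers
  auto gid = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * k);
  };

  int corner_off[8][3];
  for (int c = 0; c < 8; ++c) {
    corner_off[c][0] = c & 1;
    corner_off[c][1] = (c >> 1) & 1;
    corner_off[c][2] = (c >> 2) & 1;
  }

  // endpoints must arrive ordered by gid (see edge_point_ord)
  auto edge_point = [&](int64_t ga, int64_t gb, double va, double vb,
                        const V3& pa, const V3& pb) -> int {
    uint64_t key = ((uint64_t)ga << 32) | (uint64_t)(uint32_t)gb;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = va / (va - vb);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    V3 p = pa + t * (pb - pa);
    verts.push_back(p.x); verts.push_back(p.y); verts.push_back(p.z);
    int id = (int)(verts.size() / 3); // 1-based
    edge_vertex.emplace(key, id);
    return id;
  };

  // wrapper that orders endpoints by gid before interpolation so the cached
  // vertex is identical regardless of traversal direction
  auto edge_point_ord = [&](int64_t ga, int64_t gb, double va, double vb,
                            V3 pa, V3 pb) -> int {
    if (ga > gb) { std::swap(ga, gb); std::swap(va, vb); std::swap(pa, pb); }
    return edge_point(ga, gb, va, vb, pa, pb);
  };

  auto vert_pos = [&](int id) -> V3 {
    return {verts[3 * (id - 1)], verts[3 * (id - 1) + 1], verts[3 * (id - 1) + 2]};
  };

  auto push_tri = [&](int a, int b, int c, const V3& inside_ref, bool ref_is_inside) {
    V3 pa = vert_pos(a), pb = vert_pos(b), pc = vert_pos(c);
    V3 n = cross(pb - pa, pc - pa);
    // zero-area slivers are kept (dropping them would open the surface);
    // their orientation is immaterial
    V3 cen = (1.0 / 3.0) * (pa + pb + pc);
    double s = dot(n, inside_ref - cen);
    // normal must point away from the inside region
    bool flip = ref_is_inside ? (s > 0) : (s < 0);
    if (flip) { faces.push_back(a); faces.push_back(c); faces.push_back(b); }
    else      { faces.push_back(a); faces.push_back(b); faces.push_back(c); }
  };

  int64_t cg[8];
  double cv[8];
  V3 cp[8];

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      const double* slab0 = val + (int64_t)nx * ((int64_t)j + (int64_t)ny * k);
      for (int i = 0; i + 1 < nx; ++i) {
        // quick reject on the cube
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + corner_off[c][0], jj = j + corner_off[c][1], kk = k + corner_off[c][2];
          double v = val[gid(ii, jj, kk)];
          if (v == 0.0) v = 1e-12;
          cv[c] = v;
          if (v < 0) any_in = true; else any_out = true;
        }
        (void)slab0;
        if (!any_in || !any_out) continue;
        for (int c = 0; c < 8; ++c) {
          int ii = i + corner_off[c][0], jj = j + corner_off[c][1], kk = k + corner_off[c][2];
          cg[c] = gid(ii, jj, kk);
          cp[c] = {ox + hx * ii, oy + hy * jj, oz + hz * kk};
        }
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int ins[4], outs[4];
          int ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (cv[T[c]] < 0) ins[ni++] = T[c]; else outs[no++] = T[c];
          }
          if (ni == 0 || ni == 4) continue;
          if (ni == 1) {
            int I = ins[0];
            int e1 = edge_point_ord(cg[I], cg[outs[0]], cv[I], cv[outs[0]], cp[I], cp[outs[0]]);
            int e2 = edge_point_ord(cg[I], cg[outs[1]], cv[I], cv[outs[1]], cp[I], cp[outs[1]]);
            int e3 = edge_point_ord(cg[I], cg[outs[2]], cv[I], cv[outs[2]], cp[I], cp[outs[2]]);
            push_tri(e1, e2, e3, cp[I], true);
          } else if (ni == 3) {
            int O = outs[0];
            int e1 = edge_point_ord(cg[O], cg[ins[0]], cv[O], cv[ins[0]], cp[O], cp[ins[0]]);
            int e2 = edge_point_ord(cg[O], cg[ins[1]], cv[O], cv[ins[1]], cp[O], cp[ins[1]]);
            int e3 = edge_point_ord(cg[O], cg[ins[2]], cv[O], cv[ins[2]], cp[O], cp[ins[2]]);
            push_tri(e1, e2, e3, cp[O], false);
          } else { // 2-2: quad AC, AD, BD, BC (A,B inside; C,D outside)
            int A = ins[0], B = ins[1], C = outs[0], D = outs[1];
            int eac = edge_point_ord(cg[A], cg[C], cv[A], cv[C], cp[A], cp[C]);
            int ead = edge_point_ord(cg[A], cg[D], cv[A], cv[D], cp[A], cp[D]);
            int ebd = edge_point_ord(cg[B], cg[D], cv[B], cv[D], cp[B], cp[D]);
            int ebc = edge_point_ord(cg[B], cg[C], cv[B], cv[C], cp[B], cp[C]);
            V3 mid_in = 0.5 * (cp[A] + cp[B]);
            push_tri(eac, ead, ebd, mid_in, true);
            push_tri(eac, ebd, ebc, mid_in, true);
          }
        }
      }
    }
  }

  R_xlen_t nv = verts.size() / 3, nf = faces.size() / 3;
  NumericMatrix Vm(nv, 3);
  for (R_xlen_t r = 0; r < nv; ++r) {
    Vm(r, 0) = verts[3 * r]; Vm(r, 1) = verts[3 * r + 1]; Vm(r, 2) = verts[3 * r + 2];
  }
  IntegerMatrix Fm(nf, 3);
  for (R_xlen_t r = 0; r < nf; ++r) {
    Fm(r, 0) = faces[3 * r]; Fm(r, 1) = faces[3 * r + 1]; Fm(r, 2) = faces[3 * r + 2];
  }
  return List::create(_["vertices"] = Vm, _["faces"] = Fm);
}

// ---------------------------------------------------------------------------
// Closest point on mesh (uniform grid over triangle bounding boxes)
// ---------------------------------------------------------------------------

namespace {

// Ericson, Real-Time Collision Detection, closest point on triangle
inline V3 closest_on_tri(const V3& p, const V3& a, const V3& b, const V3& c) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return a;
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    return a + v * ab;
  }
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    return a + w * ac;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + w * (c - b);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + v * ab + w * ac;
}

struct MeshGrid {
  std::vector<V3> A, B, C;      // triangle vertices
  int gx, gy, gz;
  double x0, y0, z0, cx, cy, cz; // origin and cell size
  std::vector<std::vector<int>> cells;

  int cell_id(int i, int j, int k) const { return i + gx * (j + gy * k); }

  void build(const NumericMatrix& V, const IntegerMatrix& F) {
    int nf = F.nrow();
    A.resize(nf); B.resize(nf); C.resize(nf);
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int r = 0; r < V.nrow(); ++r) {
      for (int d = 0; d < 3; ++d) {
        double v = V(r, d);
        if (v < lo[d]) lo[d] = v;
        if (v > hi[d]) hi[d] = v;
      }
    }
    double ext[3];
    for (int d = 0; d < 3; ++d) ext[d] = std::max(hi[d] - lo[d], 1e-9);
    double target = std::cbrt((double)nf);
    int g = std::max(4, std::min(160, (int)target));
    // roughly isotropic cells
    double diag = std::max({ext[0], ext[1], ext[2]});
    double cell = diag / g;
    gx = std::max(1, (int)std::ceil(ext[0] / cell));
    gy = std::max(1, (int)std::ceil(ext[1] / cell));
    gz = std::max(1, (int)std::ceil(ext[2] / cell));
    x0 = lo[0]; y0 = lo[1]; z0 = lo[2];
    cx = ext[0] / gx; cy = ext[1] / gy; cz = ext[2] / gz;
    cells.assign((size_t)gx * gy * gz, {});
    for (int f = 0; f < nf; ++f) {
      A[f] = {V(F(f, 0) - 1, 0), V(F(f, 0) - 1, 1), V(F(f, 0) - 1, 2)};
      B[f] = {V(F(f, 1) - 1, 0), V(F(f, 1) - 1, 1), V(F(f, 1) - 1, 2)};
      C[f] = {V(F(f, 2) - 1, 0), V(F(f, 2) - 1, 1), V(F(f, 2) - 1, 2)};
      double tlo[3] = {std::min({A[f].x, B[f].x, C[f].x}),
                       std::min({A[f].y, B[f].y, C[f].y}),
                       std::min({A[f].z, B[f].z, C[f].z})};
      double thi[3] = {std::max({A[f].x, B[f].x, C[f].x}),
                       std::max({A[f].y, B[f].y, C[f].y}),
                       std::max({A[f].z, B[f].z, C[f].z})};
      int i0 = clampi((int)std::floor((tlo[0] - x0) / cx), 0, gx - 1);
      int i1 = clampi((int)std::floor((thi[0] - x0) / cx), 0, gx - 1);
      int j0 = clampi((int)std::floor((tlo[1] - y0) / cy), 0, gy - 1);
      int j1 = clampi((int)std::floor((thi[1] - y0) / cy), 0, gy - 1);
      int k0 = clampi((int)std::floor((tlo[2] - z0) / cz), 0, gz - 1);
      int k1 = clampi((int)std::floor((thi[2] - z0) / cz), 0, gz - 1);
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i)
            cells[cell_id(i, j, k)].push_back(f);
    }
  }

  static int clampi(int v, int lo, int hi) { return v < lo ? lo : (v > hi ? hi : v); }

  void query(const V3& p, double& best_d2, int& best_f, V3& best_p) const {
    int ci = clampi((int)std::floor((p.x - x0) / cx), 0, gx - 1);
    int cj = clampi((int)std::floor((p.y - y0) / cy), 0, gy - 1);
    int ck = clampi((int)std::floor((p.z - z0) / cz), 0, gz - 1);
    best_d2 = R_PosInf; best_f = -1;
    double min_cell = std::min({cx, cy, cz});
    int max_ring = std::max({gx, gy, gz});
    for (int r = 0; r <= max_ring; ++r) {
      // cells at Chebyshev ring r
      int i0 = ci - r, i1 = ci + r, j0 = cj - r, j1 = cj + r, k0 = ck - r, k1 = ck + r;
      for (int k = k0; k <= k1; ++k) {
        if (k < 0 || k >= gz) continue;
        for (int j = j0; j <= j1; ++j) {
          if (j < 0 || j >= gy) continue;
          for (int i = i0; i <= i1; ++i) {
            if (i < 0 || i >= gx) continue;
            if (std::max({std::abs(i - ci), std::abs(j - cj), std::abs(k - ck)}) != r)
              continue;
            const std::vector<int>& lst = cells[cell_id(i, j, k)];
            for (int f : lst) {
              V3 q = closest_on_tri(p, A[f], B[f], C[f]);
              double d2 = norm2(p - q);
              if (d2 < best_d2) { best_d2 = d2; best_f = f; best_p = q; }
            }
          }
        }
      }
      if (best_f >= 0 && best_d2 <= (double)r * min_cell * (double)r * min_cell)
        break;
    }
  }
};

} // namespace

static List grid_query_all(const MeshGrid& g, const NumericMatrix& Q) {
  int n = Q.nrow();
  NumericMatrix P(n, 3);
  NumericVector D(n);
  IntegerVector Fi(n);
  for (int r = 0; r < n; ++r) {
    V3 p = {Q(r, 0), Q(r, 1), Q(r, 2)};
    double d2; int f; V3 cp = p;
    g.query(p, d2, f, cp);
    P(r, 0) = cp.x; P(r, 1) = cp.y; P(r, 2) = cp.z;
    D[r] = std::sqrt(d2);
    Fi[r] = f + 1;
  }
  return List::create(_["points"] = P, _["dist"] = D, _["face"] = Fi);
}

// [[Rcpp::export(name = ".cpp_closest_points")]]
List closest_points(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  MeshGrid g;
  g.build(V, F);
  return grid_query_all(g, Q);
}

// persistent index for repeated queries against the same mesh
// [[Rcpp::export(name = ".cpp_cp_index")]]
SEXP cp_index(NumericMatrix V, IntegerMatrix F) {
  XPtr<MeshGrid> p(new MeshGrid(), true);
  p->build(V, F);
  return p;
}

// [[Rcpp::export(name = ".cpp_cp_query")]]
List cp_query(SEXP ptr, NumericMatrix Q) {
  XPtr<MeshGrid> p(ptr);
  return grid_query_all(*p, Q);
}

// ---------------------------------------------------------------------------
// Ray casting (Moller-Trumbore, brute force over triangles per ray)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_ray_mesh")]]
List ray_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix orig,
              NumericMatrix dir, double tmax) {
  int nf = F.nrow(), nr = orig.nrow();
  std::vector<V3> A(nf), E1(nf), E2(nf);
  for (int f = 0; f < nf; ++f) {
    V3 a = {V(F(f, 0) - 1, 0), V(F(f, 0) - 1, 1), V(F(f, 0) - 1, 2)};
    V3 b = {V(F(f, 1) - 1, 0), V(F(f, 1) - 1, 1), V(F(f, 1) - 1, 2)};
    V3 c = {V(F(f, 2) - 1, 0), V(F(f, 2) - 1, 1), V(F(f, 2) - 1, 2)};
    A[f] = a; E1[f] = b - a; E2[f] = c - a;
  }
  NumericVector tfirst(nr);
  IntegerVector count(nr), face_first(nr);
  const double eps = 1e-12;
  for (int r = 0; r < nr; ++r) {
    V3 o = {orig(r, 0), orig(r, 1), orig(r, 2)};
    V3 d = {dir(r, 0), dir(r, 1), dir(r, 2)};
    double tbest = R_PosInf;
    int cnt = 0, fbest = 0;
    for (int f = 0; f < nf; ++f) {
      V3 pvec = cross(d, E2[f]);
      double det = dot(E1[f], pvec);
      if (std::abs(det) < eps) continue;
      double inv = 1.0 / det;
      V3 tvec = o - A[f];
      double u = dot(tvec, pvec) * inv;
      if (u < 0 || u > 1) continue;
      V3 qvec = cross(tvec, E1[f]);
      double v = dot(d, qvec) * inv;
      if (v < 0 || u + v > 1) continue;
      double t = dot(E2[f], qvec) * inv;
      if (t > 1e-9 && t <= tmax) {
        ++cnt;
        if (t < tbest) { tbest = t; fbest = f + 1; }
      }
    }
    tfirst[r] = (cnt > 0) ? tbest : NA_REAL;
    count[r] = cnt;
    face_first[r] = (cnt > 0) ? fbest : NA_INTEGER;
  }
  return List::create(_["t"] = tfirst, _["count"] = count, _["face"] = face_first);
}

// ---------------------------------------------------------------------------
// Directed-edge audit (watertightness / orientation / manifoldness)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_edge_audit")]]
List edge_audit(IntegerMatrix F, int nvert) {
  std::unordered_map<uint64_t, int> fwd, bwd; // directed edge counts
  int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    int v[3] = {F(f, 0), F(f, 1), F(f, 2)};
    for (int e = 0; e < 3; ++e) {
      int a = v[e], b = v[(e + 1) % 3];
      if (a < 1 || b < 1 || a > nvert || b > nvert)
        stop("face references vertex out of range");
      if (a == b) stop("degenerate face with repeated vertex");
      uint64_t key = a < b ? (((uint64_t)a << 32) | (uint32_t)b)
                           : (((uint64_t)b << 32) | (uint32_t)a);
      if (a < b) fwd[key]++; else bwd[key]++;
    }
  }
  long boundary = 0, nonmanifold = 0, misoriented = 0, nedges = 0;
  std::unordered_map<uint64_t, int> all;
  for (auto& kv : fwd) all[kv.first] += kv.second;
  for (auto& kv : bwd) all[kv.first] += kv.second;
  for (auto& kv : all) {
    ++nedges;
    int tot = kv.second;
    int nf_ = 0, nb_ = 0;
    auto itf = fwd.find(kv.first);
    if (itf != fwd.end()) nf_ = itf->second;
    auto itb = bwd.find(kv.first);
    if (itb != bwd.end()) nb_ = itb->second;
    if (tot == 1) ++boundary;
    else if (tot > 2) ++nonmanifold;
    else if (nf_ != 1 || nb_ != 1) ++misoriented;
  }
  bool closed = (boundary == 0 && nonmanifold == 0 && misoriented == 0);
  return List::create(_["closed"] = closed,
                      _["n_edges"] = (double)nedges,
                      _["n_boundary"] = (double)boundary,
                      _["n_nonmanifold"] = (double)nonmanifold,
                      _["n_misoriented"] = (double)misoriented);
}
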
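#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Marching tetrahedra isosurface extraction.
//
// The scalar field is an R 3D array with dim (d1, d2, d3); lattice point
// (a, b, c) (0-based) has linear index a + d1*(b + d2*c).  Each grid cube is
// split into six tetrahedra sharing the body diagonal v0-v6, a decomposition
// whose face diagonals match between neighbouring cubes, so the welded mesh
// is watertight.  Triangle orientation is fixed locally so normals point from
// the inside (field > iso) toward the outside.
// ---------------------------------------------------------------------------

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 vsub(const Vec3 &a, const Vec3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 vadd(const Vec3 &a, const Vec3 &b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 vscale(const Vec3 &a, double s) { return {a.x * s, a.y * s, a.z * s}; }
inline double vdot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double vnorm2(const Vec3 &a) { return vdot(a, a); }

// cube corner offsets, corner index n: (x, y, z) in {0,1}^3
const int CORNER[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};

// six tetrahedra around the v0-v6 body diagonal
const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};

struct MeshBuilder {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<Vec3> verts;
  std::vector<int> tris;  // 0-based vertex indices, 3 per triangle
  uint64_t npoints;

  // vertex on the lattice edge (la, lb), interpolated at the iso crossing
  int edge_point(uint64_t la, uint64_t lb, const Vec3 &pa, const Vec3 &pb,
                 double fa, double fb, double iso) {
    uint64_t lo = la < lb ? la : lb, hi = la < lb ? lb : la;
    uint64_t key = lo * npoints + hi;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double denom = fb - fa;
    double t = denom != 0.0 ? (iso - fa) / denom : 0.5;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    Vec3 p = vadd(pa, vscale(vsub(pb, pa), t));
    int id = (int)verts.size();
    verts.push_back(p);
    edge_vertex[key] = id;
    return id;
  }

  // add triangle (i, j, k), flipping so the normal has positive dot with
  // `outward` taken from the triangle centroid
  void add_tri(int i, int j, int k, const Vec3 &out_ref, bool ref_is_outside) {
    Vec3 a = verts[i], b = verts[j], c = verts[k];
    Vec3 n = vcross(vsub(b, a), vsub(c, a));
    Vec3 cen = vscale(vadd(vadd(a, b), c), 1.0 / 3.0);
    double d = vdot(n, vsub(out_ref, cen));
    bool flip = ref_is_outside ? (d < 0.0) : (d > 0.0);
    if (flip) {
      tris.push_back(i); tris.push_back(k); tris.push_back(j);
    } else {
      tris.push_back(i); tris.push_back(j); tris.push_back(k);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_marching_tetrahedra(NumericVector field, double iso) {
  IntegerVector dim = field.attr("dim");
  if (dim.size() != 3) stop("field must be a 3D array");
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const double *f = REAL(field);

  MeshBuilder mb;
  mb.npoints = (uint64_t)d1 * d2 * d3;

  uint64_t lin[8];
  Vec3 pos[8];
  double val[8];

  for (int c = 0; c + 1 < d3; ++c) {
    for (int b = 0; b + 1 < d2; ++b) {
      for (int a = 0; a + 1 < d1; ++a) {
        bool any_in = false, any_out = false;
        for (int n = 0; n < 8; ++n) {
          int aa = a + CORNER[n][0], bb = b + CORNER[n][1], cc = c + CORNER[n][2];
          lin[n] = (uint64_t)aa + (uint64_t)d1 * ((uint64_t)bb + (uint64_t)d2 * cc);
          val[n] = f[lin[n]];
          pos[n] = {(double)aa, (double)bb, (double)cc};
          if (val[n] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          int vi[4] = {TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3]};
          int inside[4], nin = 0, nout = 0;
          int ins[4], outs[4];
          for (int k = 0; k < 4; ++k) {
            inside[k] = val[vi[k]] > iso;
            if (inside[k]) ins[nin++] = vi[k]; else outs[nout++] = vi[k];
          }
          if (nin == 0 || nin == 4) continue;

          if (nin == 1) {
            int A = ins[0];
            int e0 = mb.edge_point(lin[A], lin[outs[0]], pos[A], pos[outs[0]], val[A], val[outs[0]], iso);
            int e1 = mb.edge_point(lin[A], lin[outs[1]], pos[A], pos[outs[1]], val[A], val[outs[1]], iso);
            int e2 = mb.edge_point(lin[A], lin[outs[2]], pos[A], pos[outs[2]], val[A], val[outs[2]], iso);
            mb.add_tri(e0, e1, e2, pos[A], false);
          } else if (nin == 3) {
            int D = outs[0];
            int e0 = mb.edge_point(lin[ins[0]], lin[D], pos[ins[0]], pos[D], val[ins[0]], val[D], iso);
            int e1 = mb.edge_point(lin[ins[1]], lin[D], pos[ins[1]], pos[D], val[ins[1]], val[D], iso);
            int e2 = mb.edge_point(lin[ins[2]], lin[D], pos[ins[2]], pos[D], val[ins[2]], val[D], iso);
            mb.add_tri(e0, e1, e2, pos[D], true);
          } else {  // nin == 2: quad split into two triangles
            int A = ins[0], B = ins[1], C = outs[0], D = outs[1];
            int eAC = mb.edge_point(lin[A], lin[C], pos[A], pos[C], val[A], val[C], iso);
            int eAD = mb.edge_point(lin[A], lin[D], pos[A], pos[D], val[A], val[D], iso);
            int eBD = mb.edge_point(lin[B], lin[D], pos[B], pos[D], val[B], val[D], iso);
            int eBC = mb.edge_point(lin[B], lin[C], pos[B], pos[C], val[B], val[C], iso);
            Vec3 mid_out = vscale(vadd(pos[C], pos[D]), 0.5);
            mb.add_tri(eAC, eAD, eBD, mid_out, true);
            mb.add_tri(eAC, eBD, eBC, mid_out, true);
          }
        }
      }
    }
  }

  const int nv = (int)mb.verts.size();
  const int nt = (int)(mb.tris.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = mb.verts[i].x;
    V(i, 1) = mb.verts[i].y;
    V(i, 2) = mb.verts[i].z;
  }
  IntegerMatrix T(nt, 3);
  for (int i = 0; i < nt; ++i) {
    T(i, 0) = mb.tris[3 * i] + 1;      // 1-based for R
    T(i, 1) = mb.tris[3 * i + 1] + 1;
    T(i, 2) = mb.tris[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = T);
}

// ---------------------------------------------------------------------------
// Exact closest point on a triangle (Ericson, Real-Time Collision Detection).
// ---------------------------------------------------------------------------

namespace {

Vec3 closest_on_triangle(const Vec3 &p, const Vec3 &a, const Vec3 &b, const Vec3 &c) {
  Vec3 ab = vsub(b, a), ac = vsub(c, a), ap = vsub(p, a);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;

  Vec3 bp = vsub(p, b);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return vadd(a, vscale(ab, v));
  }

  Vec3 cp = vsub(p, c);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return vadd(a, vscale(ac, w));
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return vadd(b, vscale(vsub(c, b), w));
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return vadd(a, vadd(vscale(ab, v), vscale(ac, w)));
}

}  // namespace

// For each query point, the exact nearest point over all mesh triangles.
// Triangles are culled with a bounding-sphere test against the best distance
// found so far (seeded by a nearest-vertex pass), so typical queries touch a
// small fraction of the mesh.
// [[Rcpp::export]]
List cpp_nearest_on_mesh(NumericMatrix points, NumericMatrix vertices, IntegerMatrix triangles) {
  const int np = points.nrow();
  const int nt = triangles.nrow();
  const int nv = vertices.nrow();
  if (nt == 0 || nv == 0) stop("mesh is empty");

  std::vector<Vec3> V(nv);
  for (int i = 0; i < nv; ++i) V[i] = {vertices(i, 0), vertices(i, 1), vertices(i, 2)};

  std::vector<Vec3> cen(nt);
  std::vector<double> rad(nt);
  for (int t = 0; t < nt; ++t) {
    Vec3 a = V[triangles(t, 0) - 1], b = V[triangles(t, 1) - 1], c = V[triangles(t, 2) - 1];
    Vec3 g = vscale(vadd(vadd(a, b), c), 1.0 / 3.0);
    cen[t] = g;
    double r2 = std::max(vnorm2(vsub(a, g)), std::max(vnorm2(vsub(b, g)), vnorm2(vsub(c, g))));
    rad[t] = std::sqrt(r2);
  }

  NumericMatrix out(np, 3);
  NumericVector dist(np);
  for (int i = 0; i < np; ++i) {
    Vec3 p = {points(i, 0), points(i, 1), points(i, 2)};
    double best2 = R_PosInf;
    for (int v = 0; v < nv; ++v) {
      double d2 = vnorm2(vsub(V[v], p));
      if (d2 < best2) best2 = d2;
    }
    double best = std::sqrt(best2);
    Vec3 bp = p;
    bool found = false;
    for (int t = 0; t < nt; ++t) {
      double dc = std::sqrt(vnorm2(vsub(cen[t], p)));
      if (dc - rad[t] > best) continue;
      Vec3 q = closest_on_triangle(p, V[triangles(t, 0) - 1], V[triangles(t, 1) - 1],
                                   V[triangles(t, 2) - 1]);
      double d2 = vnorm2(vsub(q, p));
      if (d2 <= best2) {
        best2 = d2;
        best = std::sqrt(d2);
        bp = q;
        found = true;
      }
    }
    if (!found) {
      // best was attained at a vertex excluded by <=; rescan without culling
      for (int t = 0; t < nt; ++t) {
        Vec3 q = closest_on_triangle(p, V[triangles(t, 0) - 1], V[triangles(t, 1) - 1],
                                     V[triangles(t, 2) - 1]);
        double d2 = vnorm2(vsub(q, p));
        if (d2 <= best2) { best2 = d2; bp = q; }
      }
    }
    out(i, 0) = bp.x;
    out(i, 1) = bp.y;
    out(i, 2) = bp.z;
    dist[i] = std::sqrt(best2);
  }
  return List::create(_["point"] = out, _["distance"] = dist);
}

// ---------------------------------------------------------------------------
// Nearest-seed assignment for Voronoi phantom labelling: for each foreground
// voxel (physical coordinates), the 1-based index of the closest seed point.
// Spatial coherence: each voxel starts from the previous voxel's winner, and
// per-seed evaluation bails out component-wise once the running best is beaten.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_nearest_seed(NumericMatrix voxels, NumericMatrix seeds) {
  const int nv = voxels.nrow(), ns = seeds.nrow();
  if (ns == 0) stop("no seeds");
  std::vector<double> sx(ns), sy(ns), sz(ns);
  for (int s = 0; s < ns; ++s) { sx[s] = seeds(s, 0); sy[s] = seeds(s, 1); sz[s] = seeds(s, 2); }

  IntegerVector out(nv);
  int prev = 0;
  for (int i = 0; i < nv; ++i) {
    const double px = voxels(i, 0), py = voxels(i, 1), pz = voxels(i, 2);
    double dx = px - sx[prev], dy = py - sy[prev], dz = pz - sz[prev];
    double best = dx * dx + dy * dy + dz * dz;
    int who = prev;
    for (int s = 0; s < ns; ++s) {
      if (s == prev) continue;
      double d = px - sx[s]; d *= d;
      if (d >= best) continue;
      double e = py - sy[s]; d += e * e;
      if (d >= best) continue;
      e = pz - sz[s]; d += e * e;
      if (d < best) { best = d; who = s; }
    }
    out[i] = who + 1;
    prev = who;
  }
  return out;
}
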
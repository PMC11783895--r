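#include <Rcpp.h>
#include <cmath>
#include <map>
#include <vector>
using namespace Rcpp;

// Molecular envelope triangulation by marching tetrahedra on a regular
// lattice. The scalar field is the signed distance to the union of atom
// spheres, f(x) = min_i(|x - c_i| - r_i); the surface is the f = 0 level set.
// Each lattice cube is split into 6 tetrahedra sharing the main diagonal,
// which yields a watertight, consistently interpolated triangulation without
// the case-table ambiguities of cube-based extraction.

struct EdgeKey {
  long a, b;
  bool operator<(const EdgeKey &o) const {
    return a < o.a || (a == o.a && b < o.b);
  }
};

// [[Rcpp::export(name = ".surface_mesh_cpp")]]
List surface_mesh_cpp(NumericMatrix coords, NumericVector radii,
                      double spacing, double pad) {
  const int na = coords.nrow();
  double mn[3], mx[3];
  for (int k = 0; k < 3; ++k) { mn[k] = R_PosInf; mx[k] = R_NegInf; }
  double rmax = 0;
  for (int a = 0; a < na; ++a) {
    rmax = std::max(rmax, radii[a]);
    for (int k = 0; k < 3; ++k) {
      mn[k] = std::min(mn[k], coords(a, k));
      mx[k] = std::max(mx[k], coords(a, k));
    }
  }
  double lo[3];
  int np[3];  // lattice points per axis
  for (int k = 0; k < 3; ++k) {
    lo[k] = mn[k] - rmax - pad;
    double hi = mx[k] + rmax + pad;
    np[k] = (int)std::ceil((hi - lo[k]) / spacing) + 1;
  }
  const long NX = np[0], NY = np[1], NZ = np[2];
  std::vector<double> F((size_t)(NX * NY * NZ));
  for (long z = 0; z < NZ; ++z)
    for (long y = 0; y < NY; ++y)
      for (long x = 0; x < NX; ++x) {
        double px = lo[0] + x * spacing, py = lo[1] + y * spacing,
               pz = lo[2] + z * spacing;
        double f = R_PosInf;
        for (int a = 0; a < na; ++a) {
          double dx = px - coords(a, 0), dy = py - coords(a, 1),
                 dz = pz - coords(a, 2);
          f = std::min(f, std::sqrt(dx * dx + dy * dy + dz * dz) - radii[a]);
        }
        F[(size_t)((z * NY + y) * NX + x)] = f == 0 ? 1e-12 : f;
      }
  auto gid = [&](long x, long y, long z) { return (z * NY + y) * NX + x; };
  // 6 tetrahedra per cube around the 0-7 main diagonal (corner bit order xyz)
  static const int tets[6][4] = {{0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
                                 {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  std::map<EdgeKey, int> vmap;
  std::vector<double> verts;
  std::vector<int> faces;
  auto vertex_on_edge = [&](long g1, long g2) {
    EdgeKey k{std::min(g1, g2), std::max(g1, g2)};
    auto it = vmap.find(k);
    if (it != vmap.end()) return it->second;
    double f1 = F[(size_t)k.a], f2 = F[(size_t)k.b];
    double t = f1 / (f1 - f2);
    long a = k.a, b = k.b;
    long az = a / (NX * NY), ay = (a / NX) % NY, ax = a % NX;
    long bz = b / (NX * NY), by = (b / NX) % NY, bx = b % NX;
    double p[3] = {lo[0] + (ax + t * (bx - ax)) * spacing,
                   lo[1] + (ay + t * (by - ay)) * spacing,
                   lo[2] + (az + t * (bz - az)) * spacing};
    int id = (int)(verts.size() / 3);
    verts.insert(verts.end(), p, p + 3);
    vmap[k] = id;
    return id;
  };
  long corner[8];
  for (long z = 0; z + 1 < NZ; ++z)
    for (long y = 0; y + 1 < NY; ++y)
      for (long x = 0; x + 1 < NX; ++x) {
        for (int c = 0; c < 8; ++c)
          corner[c] = gid(x + (c & 1), y + ((c >> 1) & 1), z + ((c >> 2) & 1));
        for (int t = 0; t < 6; ++t) {
          long g[4];
          bool in[4];
          int nin = 0;
          for (int v = 0; v < 4; ++v) {
            g[v] = corner[tets[t][v]];
            in[v] = F[(size_t)g[v]] < 0;
            nin += in[v];
          }
          if (nin == 0 || nin == 4) continue;
          int ins[4], outs[4], ni = 0, no = 0;
          for (int v = 0; v < 4; ++v) (in[v] ? ins[ni++] : outs[no++]) = v;
          if (nin == 1) {
            int v0 = vertex_on_edge(g[ins[0]], g[outs[0]]);
            int v1 = vertex_on_edge(g[ins[0]], g[outs[1]]);
            int v2 = vertex_on_edge(g[ins[0]], g[outs[2]]);
            faces.insert(faces.end(), {v0, v1, v2});
          } else if (nin == 3) {
            int v0 = vertex_on_edge(g[outs[0]], g[ins[0]]);
            int v1 = vertex_on_edge(g[outs[0]], g[ins[1]]);
            int v2 = vertex_on_edge(g[outs[0]], g[ins[2]]);
            faces.insert(faces.end(), {v0, v1, v2});
          } else {  // 2 in, 2 out: quad split into two triangles
            int e00 = vertex_on_edge(g[ins[0]], g[outs[0]]);
            int e01 = vertex_on_edge(g[ins[0]], g[outs[1]]);
            int e10 = vertex_on_edge(g[ins[1]], g[outs[0]]);
            int e11 = vertex_on_edge(g[ins[1]], g[outs[1]]);
            faces.insert(faces.end(), {e00, e01, e11});
            faces.insert(faces.end(), {e00, e11, e10});
          }
        }
      }
  const int nv = (int)(verts.size() / 3), nf = (int)(faces.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) V(i, k) = verts[3 * i + k];
  IntegerMatrix Fc(nf, 3);
  for (int i = 0; i < nf; ++i)
    for (int k = 0; k < 3; ++k) Fc(i, k) = faces[3 * i + k] + 1;  // 1-based
  return List::create(_["vertices"] = V, _["faces"] = Fc);
}
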
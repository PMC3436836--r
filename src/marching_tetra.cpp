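#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Iso-surface extraction at level 0 from a scalar field sampled on a regular
// grid, by marching tetrahedra: each grid cube is split into the six Kuhn
// tetrahedra around the main diagonal, so face diagonals agree between
// neighbouring cubes and the output is a closed, conforming triangle mesh
// whenever the field is negative inside and positive outside with no zeros
// on grid nodes (callers perturb exact zeros).
//
// field: nx*ny*nz values, x fastest (R array order).
// Returns vertices (m x 3) and 1-based triangle indices (k x 3), oriented so
// that triangle normals point from the negative (inside) region outwards.

static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

struct MeshAcc {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
};

static inline int edge_point(MeshAcc &acc, int a, int b,
                             const std::vector<double> &px,
                             const std::vector<double> &py,
                             const std::vector<double> &pz,
                             const double *f) {
  if (a > b) std::swap(a, b);
  uint64_t key = (uint64_t)a * 0x100000000ULL + (uint64_t)b;
  auto it = acc.edge_vertex.find(key);
  if (it != acc.edge_vertex.end()) return it->second;
  double fa = f[a], fb = f[b];
  double t = fa / (fa - fb);
  int id = (int)acc.vx.size();
  acc.vx.push_back(px[a] + t * (px[b] - px[a]));
  acc.vy.push_back(py[a] + t * (py[b] - py[a]));
  acc.vz.push_back(pz[a] + t * (pz[b] - pz[a]));
  acc.edge_vertex[key] = id;
  return id;
}

static inline void push_tri(MeshAcc &acc, int v0, int v1, int v2,
                            double dx, double dy, double dz) {
  // orient so cross(e1, e2) . (neg -> pos direction) > 0 (outward normal)
  double ax = acc.vx[v1] - acc.vx[v0], ay = acc.vy[v1] - acc.vy[v0],
         az = acc.vz[v1] - acc.vz[v0];
  double bx = acc.vx[v2] - acc.vx[v0], by = acc.vy[v2] - acc.vy[v0],
         bz = acc.vz[v2] - acc.vz[v0];
  double nx = ay * bz - az * by, ny = az * bx - ax * bz, nz = ax * by - ay * bx;
  if (nx * dx + ny * dy + nz * dz < 0) std::swap(v1, v2);
  acc.tri.push_back(v0); acc.tri.push_back(v1); acc.tri.push_back(v2);
}

// [[Rcpp::export(name = ".march_tetra")]]
List march_tetra(NumericVector field, IntegerVector counts,
                 NumericVector origin, NumericVector spacing) {
  const int nx = counts[0], ny = counts[1], nz = counts[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (field.size() != n) stop("field length does not match counts");
  std::vector<double> f(n), px(n), py(n), pz(n);
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    double v = field[idx];
    f[idx] = (v == 0.0) ? 1e-10 : v;  // avoid zeros on grid nodes
    int i = (int)(idx % nx), j = (int)((idx / nx) % ny), k = (int)(idx / ((R_xlen_t)nx * ny));
    px[idx] = origin[0] + spacing[0] * i;
    py[idx] = origin[1] + spacing[1] * j;
    pz[idx] = origin[2] + spacing[2] * k;
  }
  MeshAcc acc;
  const double *fp = f.data();
  int corner_off[8];
  for (int c = 0; c < 8; ++c)
    corner_off[c] = (c & 1) + nx * ((c >> 1) & 1) + nx * ny * ((c >> 2) & 1);

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        R_xlen_t base = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        // skip cubes with all corners same sign
        bool any_neg = false, any_pos = false;
        for (int c = 0; c < 8; ++c) {
          double v = f[base + corner_off[c]];
          if (v < 0) any_neg = true; else any_pos = true;
        }
        if (!any_neg || !any_pos) continue;
        for (int t = 0; t < 6; ++t) {
          int g[4];
          for (int c = 0; c < 4; ++c) g[c] = (int)(base + corner_off[TETS[t][c]]);
          int neg[4], pos[4], nn = 0, np = 0;
          for (int c = 0; c < 4; ++c) {
            if (f[g[c]] < 0) neg[nn++] = g[c]; else pos[np++] = g[c];
          }
          if (nn == 0 || np == 0) continue;
          // direction from negative side to positive side (mean corners)
          double dnx = 0, dny = 0, dnz = 0;
          for (int c = 0; c < np; ++c) { dnx += px[pos[c]]; dny += py[pos[c]]; dnz += pz[pos[c]]; }
          dnx /= np; dny /= np; dnz /= np;
          double mx = 0, my = 0, mz = 0;
          for (int c = 0; c < nn; ++c) { mx += px[neg[c]]; my += py[neg[c]]; mz += pz[neg[c]]; }
          dnx -= mx / nn; dny -= my / nn; dnz -= mz / nn;
          if (nn == 1) {
            int v0 = edge_point(acc, neg[0], pos[0], px, py, pz, fp);
            int v1 = edge_point(acc, neg[0], pos[1], px, py, pz, fp);
            int v2 = edge_point(acc, neg[0], pos[2], px, py, pz, fp);
            push_tri(acc, v0, v1, v2, dnx, dny, dnz);
          } else if (np == 1) {
            int v0 = edge_point(acc, neg[0], pos[0], px, py, pz, fp);
            int v1 = edge_point(acc, neg[1], pos[0], px, py, pz, fp);
            int v2 = edge_point(acc, neg[2], pos[0], px, py, pz, fp);
            push_tri(acc, v0, v1, v2, dnx, dny, dnz);
          } else {
            // quad: crossings (a,c) (a,d) (b,d) (b,c) in cyclic order
            int a = neg[0], b = neg[1], c = pos[0], d = pos[1];
            int vac = edge_point(acc, a, c, px, py, pz, fp);
            int vad = edge_point(acc, a, d, px, py, pz, fp);
            int vbd = edge_point(acc, b, d, px, py, pz, fp);
            int vbc = edge_point(acc, b, c, px, py, pz, fp);
            push_tri(acc, vac, vad, vbd, dnx, dny, dnz);
            push_tri(acc, vac, vbd, vbc, dnx, dny, dnz);
          }
        }
      }

  int nv = (int)acc.vx.size(), nt = (int)(acc.tri.size() / 3);
  NumericMatrix verts(nv, 3);
  for (int v = 0; v < nv; ++v) {
    verts(v, 0) = acc.vx[v]; verts(v, 1) = acc.vy[v]; verts(v, 2) = acc.vz[v];
  }
  IntegerMatrix tris(nt, 3);
  for (int t2 = 0; t2 < nt; ++t2)
    for (int c = 0; c < 3; ++c) tris(t2, c) = acc.tri[3 * t2 + c] + 1;
  return List::create(_["vertices"] = verts, _["triangles"] = tris);
}

// Minimum signed distance to a set of inflated atom spheres, evaluated on a
// regular grid: f(p) = min_i (|p - c_i| - r_i) - probe.
// [[Rcpp::export(name = ".sphere_field")]]
NumericVector sphere_field(IntegerVector counts, NumericVector origin,
                           NumericVector spacing, NumericMatrix centers,
                           NumericVector radii, double probe) {
  const int nx = counts[0], ny = counts[1], nz = counts[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int na = centers.nrow();
  NumericVector out(n);
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    int i = (int)(idx % nx), j = (int)((idx / nx) % ny), k = (int)(idx / ((R_xlen_t)nx * ny));
    double x = origin[0] + spacing[0] * i;
    double y = origin[1] + spacing[1] * j;
    double z = origin[2] + spacing[2] * k;
    double best = R_PosInf;
    for (int a = 0; a < na; ++a) {
      double dx = x - centers(a, 0), dy = y - centers(a, 1), dz = z - centers(a, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz) - radii[a];
      if (d < best) best = d;
    }
    out[idx] = best - probe;
  }
  return out;
}
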
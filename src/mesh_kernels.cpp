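// Geometry kernels: binary isosurface extraction (marching tetrahedra),
// Taubin mesh smoothing, 3D connected-component labeling, ray-mesh
// intersection. All coordinates here are continuous 0-based voxel indices;
// the R layer maps them to physical millimetres through the volume affine.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// 6-tetrahedra decomposition of the unit cube around the main diagonal
// v0-v7 (corner bit order x,y,z). Face diagonals are consistent between
// neighbouring cubes, so the extracted surface is watertight.
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};

struct MeshAccum {
  std::unordered_map<uint64_t, int> edge_vertex; // (min,max grid id) -> vertex
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

// vertex on the midpoint of the grid edge (a,b); a,b linear grid ids
static int edge_vertex_id(MeshAccum& m, int64_t ga, int64_t gb,
                          const double* pa, const double* pb) {
  if (ga > gb) { std::swap(ga, gb); const double* t = pa; pa = pb; pb = t; }
  uint64_t key = (static_cast<uint64_t>(ga) << 32) | static_cast<uint64_t>(gb);
  auto it = m.edge_vertex.find(key);
  if (it != m.edge_vertex.end()) return it->second;
  int id = static_cast<int>(m.vx.size());
  m.edge_vertex.emplace(key, id);
  m.vx.push_back(0.5 * (pa[0] + pb[0]));
  m.vy.push_back(0.5 * (pa[1] + pb[1]));
  m.vz.push_back(0.5 * (pa[2] + pb[2]));
  return id;
}

static void add_tri(MeshAccum& m, int a, int b, int c,
                    const double* ref_in, const double* ref_out) {
  // orient so the normal points from the inside (mask==1) to the outside
  double p0[3] = {m.vx[a], m.vy[a], m.vz[a]};
  double e1[3] = {m.vx[b] - p0[0], m.vy[b] - p0[1], m.vz[b] - p0[2]};
  double e2[3] = {m.vx[c] - p0[0], m.vy[c] - p0[1], m.vz[c] - p0[2]};
  double n[3] = {e1[1]*e2[2] - e1[2]*e2[1],
                 e1[2]*e2[0] - e1[0]*e2[2],
                 e1[0]*e2[1] - e1[1]*e2[0]};
  double w[3] = {ref_out[0] - ref_in[0], ref_out[1] - ref_in[1],
                 ref_out[2] - ref_in[2]};
  double d = n[0]*w[0] + n[1]*w[1] + n[2]*w[2];
  if (d < 0) std::swap(b, c);
  m.f0.push_back(a); m.f1.push_back(b); m.f2.push_back(c);
}

// [[Rcpp::export]]
List mt_isosurface_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t sx = 1, sy = nx, sz = static_cast<int64_t>(nx) * ny;
  MeshAccum m;
  double corner[8][3];
  int64_t gid[8];
  bool inside[8];

  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        int any_in = 0, all_in = 1;
        for (int c = 0; c < 8; ++c) {
          int dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
          int64_t g = (i + dx) * sx + (j + dy) * sy + (k + dz) * sz;
          gid[c] = g;
          inside[c] = mask[g];
          corner[c][0] = i + dx; corner[c][1] = j + dy; corner[c][2] = k + dz;
          any_in |= inside[c]; all_in &= (int)inside[c];
        }
        if (!any_in || all_in) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int in_idx[4], out_idx[4], nin = 0, nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (inside[T[c]]) in_idx[nin++] = T[c];
            else out_idx[nout++] = T[c];
          }
          if (nin == 0 || nin == 4) continue;
          double ref_in[3] = {0, 0, 0}, ref_out[3] = {0, 0, 0};
          for (int c = 0; c < nin; ++c)
            for (int d = 0; d < 3; ++d) ref_in[d] += corner[in_idx[c]][d] / nin;
          for (int c = 0; c < nout; ++c)
            for (int d = 0; d < 3; ++d) ref_out[d] += corner[out_idx[c]][d] / nout;
          if (nin == 1) {
            int a = edge_vertex_id(m, gid[in_idx[0]], gid[out_idx[0]],
                                   corner[in_idx[0]], corner[out_idx[0]]);
            int b = edge_vertex_id(m, gid[in_idx[0]], gid[out_idx[1]],
                                   corner[in_idx[0]], corner[out_idx[1]]);
            int c = edge_vertex_id(m, gid[in_idx[0]], gid[out_idx[2]],
                                   corner[in_idx[0]], corner[out_idx[2]]);
            add_tri(m, a, b, c, ref_in, ref_out);
          } else if (nin == 3) {
            int a = edge_vertex_id(m, gid[out_idx[0]], gid[in_idx[0]],
                                   corner[out_idx[0]], corner[in_idx[0]]);
            int b = edge_vertex_id(m, gid[out_idx[0]], gid[in_idx[1]],
                                   corner[out_idx[0]], corner[in_idx[1]]);
            int c = edge_vertex_id(m, gid[out_idx[0]], gid[in_idx[2]],
                                   corner[out_idx[0]], corner[in_idx[2]]);
            add_tri(m, a, b, c, ref_in, ref_out);
          } else { // 2 in, 2 out -> quad
            int q0 = edge_vertex_id(m, gid[in_idx[0]], gid[out_idx[0]],
                                    corner[in_idx[0]], corner[out_idx[0]]);
            int q1 = edge_vertex_id(m, gid[in_idx[0]], gid[out_idx[1]],
                                    corner[in_idx[0]], corner[out_idx[1]]);
            int q2 = edge_vertex_id(m, gid[in_idx[1]], gid[out_idx[1]],
                                    corner[in_idx[1]], corner[out_idx[1]]);
            int q3 = edge_vertex_id(m, gid[in_idx[1]], gid[out_idx[0]],
                                    corner[in_idx[1]], corner[out_idx[0]]);
            add_tri(m, q0, q1, q2, ref_in, ref_out);
            add_tri(m, q0, q2, q3, ref_in, ref_out);
          }
        }
      }

  const int nv = static_cast<int>(m.vx.size());
  const int nf = static_cast<int>(m.f0.size());
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = m.vx[v]; V(v, 1) = m.vy[v]; V(v, 2) = m.vz[v];
  }
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f) {
    F(f, 0) = m.f0[f]; F(f, 1) = m.f1[f]; F(f, 2) = m.f2[f];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Taubin lambda|mu smoothing with uniform weights; 'iterations' counts
// lambda/mu pairs. Non-shrinking low-pass filter.
// [[Rcpp::export]]
NumericMatrix taubin_smooth_cpp(NumericMatrix V, IntegerMatrix F,
                                int iterations, double lambda, double mu) {
  const int nv = V.nrow(), nf = F.nrow();
  // adjacency (unique neighbours) via CSR
  std::vector<std::vector<int> > adj(nv);
  for (int f = 0; f < nf; ++f) {
    int a = F(f, 0), b = F(f, 1), c = F(f, 2);
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int v = 0; v < nv; ++v) {
    std::sort(adj[v].begin(), adj[v].end());
    adj[v].erase(std::unique(adj[v].begin(), adj[v].end()), adj[v].end());
  }
  std::vector<double> x(nv), y(nv), z(nv), x2(nv), y2(nv), z2(nv);
  for (int v = 0; v < nv; ++v) { x[v] = V(v,0); y[v] = V(v,1); z[v] = V(v,2); }
  for (int it = 0; it < iterations; ++it) {
    for (int pass = 0; pass < 2; ++pass) {
      double fct = (pass == 0) ? lambda : mu;
      for (int v = 0; v < nv; ++v) {
        const std::vector<int>& nb = adj[v];
        if (nb.empty()) { x2[v] = x[v]; y2[v] = y[v]; z2[v] = z[v]; continue; }
        double mx = 0, my = 0, mz = 0;
        for (size_t q = 0; q < nb.size(); ++q) {
          mx += x[nb[q]]; my += y[nb[q]]; mz += z[nb[q]];
        }
        double inv = 1.0 / nb.size();
        x2[v] = x[v] + fct * (mx * inv - x[v]);
        y2[v] = y[v] + fct * (my * inv - y[v]);
        z2[v] = z[v] + fct * (mz * inv - z[v]);
      }
      x.swap(x2); y.swap(y2); z.swap(z2);
    }
  }
  NumericMatrix out(nv, 3);
  for (int v = 0; v < nv; ++v) { out(v,0) = x[v]; out(v,1) = y[v]; out(v,2) = z[v]; }
  return out;
}

// Connected-component labeling of a binary 3D mask; connectivity 6 or 26.
// Returns integer labels (0 = background), numbered 1..n in scan order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = static_cast<int64_t>(nx) * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (connectivity == 6 && (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1)
          continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }
  int next_label = 0;
  std::vector<int64_t> stack;
  for (int64_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      int64_t cur = stack.back(); stack.pop_back();
      int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / (static_cast<int64_t>(nx) * ny);
      for (size_t q = 0; q < offx.size(); ++q) {
        int ii = ci + offx[q], jj = cj + offy[q], kk = ck + offz[q];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        int64_t idx = ii + static_cast<int64_t>(nx) * (jj + static_cast<int64_t>(ny) * kk);
        if (mask[idx] && labels[idx] == 0) {
          labels[idx] = next_label;
          stack.push_back(idx);
        }
      }
    }
  }
  return labels;
}

// All ray-triangle intersection distances (Moller-Trumbore), sorted
// ascending. Also returns the triangle index of each hit.
// [[Rcpp::export]]
List ray_hits_cpp(NumericMatrix V, IntegerMatrix F,
                  NumericVector orig, NumericVector dir) {
  const int nf = F.nrow();
  const double EPS = 1e-12;
  std::vector<std::pair<double,int> > hits;
  for (int f = 0; f < nf; ++f) {
    const int a = F(f,0), b = F(f,1), c = F(f,2);
    double e1[3], e2[3], pv[3], tv[3], qv[3];
    for (int d = 0; d < 3; ++d) {
      e1[d] = V(b,d) - V(a,d);
      e2[d] = V(c,d) - V(a,d);
    }
    pv[0] = dir[1]*e2[2] - dir[2]*e2[1];
    pv[1] = dir[2]*e2[0] - dir[0]*e2[2];
    pv[2] = dir[0]*e2[1] - dir[1]*e2[0];
    double det = e1[0]*pv[0] + e1[1]*pv[1] + e1[2]*pv[2];
    if (std::fabs(det) < EPS) continue;
    double inv = 1.0 / det;
    for (int d = 0; d < 3; ++d) tv[d] = orig[d] - V(a,d);
    double u = (tv[0]*pv[0] + tv[1]*pv[1] + tv[2]*pv[2]) * inv;
    if (u < -1e-9 || u > 1 + 1e-9) continue;
    qv[0] = tv[1]*e1[2] - tv[2]*e1[1];
    qv[1] = tv[2]*e1[0] - tv[0]*e1[2];
    qv[2] = tv[0]*e1[1] - tv[1]*e1[0];
    double v = (dir[0]*qv[0] + dir[1]*qv[1] + dir[2]*qv[2]) * inv;
    if (v < -1e-9 || u + v > 1 + 1e-9) continue;
    double t = (e2[0]*qv[0] + e2[1]*qv[1] + e2[2]*qv[2]) * inv;
    hits.push_back(std::make_pair(t, f));
  }
  std::sort(hits.begin(), hits.end());
  const int nh = static_cast<int>(hits.size());
  NumericVector tvals(nh);
  IntegerVector tri(nh);
  for (int h = 0; h < nh; ++h) {
    tvals[h] = hits[h].first;
    tri[h] = hits[h].second; // 0-based
  }
  return List::create(_["t"] = tvals, _["triangle"] = tri);
}
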
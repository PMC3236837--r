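// Voxel-level kernels: tube rasterization, exact Euclidean distance transform,
// center-of-mass collapse, Dijkstra over the 26-connected voxel graph,
// region growing, connected components, directional hole filling, 2-D median
// filtering, point clustering and nearest-neighbour distances.
//
// All indices are 0-based linear indices idx = x + nx*(y + ny*z); R wrappers
// convert to/from 1-based array indices.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <tuple>
#include <array>
#include <cmath>
#include <algorithm>
#include <functional>
#include <unordered_map>
using namespace Rcpp;

static const double BIGF = 1e20;

static inline void decode(R_xlen_t idx, int nx, int ny, int &x, int &y, int &z) {
  x = (int)(idx % nx);
  R_xlen_t r = idx / nx;
  y = (int)(r % ny);
  z = (int)(r / ny);
}

// 26-neighbourhood offsets (excluding self)
static void offsets26(std::vector<std::array<int,3> > &off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        off.push_back({{dx, dy, dz}});
      }
}

static void offsets6(std::vector<std::array<int,3> > &off) {
  off.clear();
  off.push_back({{ 1, 0, 0}}); off.push_back({{-1, 0, 0}});
  off.push_back({{ 0, 1, 0}}); off.push_back({{ 0,-1, 0}});
  off.push_back({{ 0, 0, 1}}); off.push_back({{ 0, 0,-1}});
}

// Mark all voxels whose centre lies within `radius` of any centreline sample.
// `samples` are continuous 0-based voxel coordinates (rows: x, y, z).
// [[Rcpp::export]]
LogicalVector cpp_rasterize_tube(IntegerVector dim, NumericMatrix samples,
                                 double radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector mask(n, false);
  double r2 = radius * radius;
  int ir = (int)std::ceil(radius);
  for (int s = 0; s < samples.nrow(); ++s) {
    double cx = samples(s, 0), cy = samples(s, 1), cz = samples(s, 2);
    int x0 = std::max(0, (int)std::ceil(cx - radius));
    int x1 = std::min(nx - 1, (int)std::floor(cx + radius));
    int y0 = std::max(0, (int)std::ceil(cy - radius));
    int y1 = std::min(ny - 1, (int)std::floor(cy + radius));
    int z0 = std::max(0, (int)std::ceil(cz - radius));
    int z1 = std::min(nz - 1, (int)std::floor(cz + radius));
    (void)ir;
    for (int z = z0; z <= z1; ++z) {
      double dz = z - cz, dz2 = dz * dz;
      for (int y = y0; y <= y1; ++y) {
        double dy = y - cy, d2 = dz2 + dy * dy;
        if (d2 > r2) continue;
        R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        for (int x = x0; x <= x1; ++x) {
          double dx = x - cx;
          if (d2 + dx * dx <= r2) mask[base + x] = true;
        }
      }
    }
  }
  return mask;
}

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher lower envelope)
// over samples at positions i*s.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n, double s) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIGF; z[1] = BIGF;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double sint;
    while (true) {
      int p = v[k];
      double xp = p * s;
      sint = ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2.0 * (xq - xp));
      if (sint <= z[k]) { --k; continue; }
      break;
    }
    ++k;
    v[k] = q; z[k] = sint; z[k + 1] = BIGF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

// Exact anisotropic Euclidean distance (physical units) from each object voxel
// to the nearest background voxel centre; 0 on background.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? BIGF : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // along x
  for (int zz = 0; zz < nz; ++zz)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * zz);
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // along y
  for (int zz = 0; zz < nz; ++zz)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * zz;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)nx * y];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)nx * y] = d[y];
    }
  // along z
  R_xlen_t plane = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      for (int zz = 0; zz < nz; ++zz) f[zz] = out[base + plane * zz];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int zz = 0; zz < nz; ++zz) out[base + plane * zz] = d[zz];
    }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// Iterative collapse of object-voxel positions toward the (optionally
// weighted) centre of mass of their 26-neighbourhood (self included);
// synchronous (Jacobi) updates. Returns the cumulative physical distance
// moved per voxel on the full grid (0 on background).
// [[Rcpp::export]]
NumericVector cpp_com_collapse(LogicalVector mask, IntegerVector dim,
                               NumericVector spacing, int iterations,
                               Nullable<NumericVector> weights_) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<R_xlen_t> vox;
  std::vector<int> comp(n, -1);
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i]) { comp[i] = (int)vox.size(); vox.push_back(i); }
  int m = (int)vox.size();
  bool wt = weights_.isNotNull();
  NumericVector W;
  if (wt) W = NumericVector(weights_);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  std::vector<double> px(m), py(m), pz(m), qx(m), qy(m), qz(m), cum(m, 0.0);
  for (int i = 0; i < m; ++i) {
    int x, y, z;
    decode(vox[i], nx, ny, x, y, z);
    px[i] = x * sx; py[i] = y * sy; pz[i] = z * sz;
  }
  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < m; ++i) {
      int x, y, z;
      decode(vox[i], nx, ny, x, y, z);
      double sw = 0.0, mx = 0.0, my = 0.0, mz = 0.0;
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          R_xlen_t base = (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            int j = comp[base + xx];
            if (j < 0) continue;
            double w = wt ? W[vox[j]] : 1.0;
            sw += w;
            mx += w * px[j]; my += w * py[j]; mz += w * pz[j];
          }
        }
      }
      if (sw > 0) { qx[i] = mx / sw; qy[i] = my / sw; qz[i] = mz / sw; }
      else { qx[i] = px[i]; qy[i] = py[i]; qz[i] = pz[i]; }
    }
    for (int i = 0; i < m; ++i) {
      double dx = qx[i] - px[i], dy = qy[i] - py[i], dz = qz[i] - pz[i];
      cum[i] += std::sqrt(dx * dx + dy * dy + dz * dz);
    }
    px.swap(qx); py.swap(qy); pz.swap(qz);
  }
  NumericVector out(n, 0.0);
  for (int i = 0; i < m; ++i) out[vox[i]] = cum[i];
  return out;
}

// Mean of `vals` over the 26-neighbourhood (self included) restricted to
// object voxels; 0 on background.
// [[Rcpp::export]]
NumericVector cpp_neighbor_mean(NumericVector vals, LogicalVector mask,
                                IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n, 0.0);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int x, y, z;
    decode(i, nx, ny, x, y, z);
    double s = 0.0;
    int cnt = 0;
    for (int dz = -1; dz <= 1; ++dz) {
      int zz = z + dz;
      if (zz < 0 || zz >= nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int yy = y + dy;
        if (yy < 0 || yy >= ny) continue;
        R_xlen_t base = (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        for (int dx = -1; dx <= 1; ++dx) {
          int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          R_xlen_t j = base + xx;
          if (!mask[j]) continue;
          s += vals[j];
          ++cnt;
        }
      }
    }
    out[i] = s / cnt;
  }
  return out;
}

// Single-source lowest-cost paths over the 26-connected object-voxel graph.
// Edge weight = mean of the endpoint voxel costs times the physical step
// length. Ties broken by insertion order (stable, deterministic).
// Returns accumulated cost, 0-based parent (-1 = none), and physical path
// length in the same units as `spacing`.
// [[Rcpp::export]]
List cpp_dijkstra(NumericVector cost, LogicalVector mask, IntegerVector dim,
                  NumericVector spacing, int goal0) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<std::array<int,3> > off;
  offsets26(off);
  double steps[26];
  for (int k = 0; k < 26; ++k) {
    double ddx = off[k][0] * spacing[0];
    double ddy = off[k][1] * spacing[1];
    double ddz = off[k][2] * spacing[2];
    steps[k] = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
  }
  NumericVector dist(n, R_PosInf), plen(n, R_PosInf);
  IntegerVector parent(n, -1);
  typedef std::tuple<double, long long, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  long long order = 0;
  dist[goal0] = 0.0;
  plen[goal0] = 0.0;
  pq.push(QE(0.0, order++, goal0));
  std::vector<char> done(n, 0);
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double d = std::get<0>(top);
    R_xlen_t u = std::get<2>(top);
    if (done[u]) continue;
    done[u] = 1;
    int x, y, z;
    decode(u, nx, ny, x, y, z);
    double cu = cost[u];
    for (int k = 0; k < 26; ++k) {
      int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t v = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (!mask[v] || done[v]) continue;
      double nd = d + 0.5 * (cu + cost[v]) * steps[k];
      if (nd < dist[v]) {
        dist[v] = nd;
        parent[v] = (int)u;
        plen[v] = plen[u] + steps[k];
        pq.push(QE(nd, order++, v));
      }
    }
  }
  for (R_xlen_t i = 0; i < n; ++i)
    if (!mask[i]) { dist[i] = NA_REAL; plen[i] = NA_REAL; }
  return List::create(_["dist"] = dist, _["parent"] = parent,
                      _["pathlen"] = plen);
}

// 26-connected region growing from seed voxels through voxels with
// intensity >= tau.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, IntegerVector dim,
                              IntegerVector seeds0, double tau) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  std::vector<std::array<int,3> > off;
  offsets26(off);
  std::vector<R_xlen_t> stack;
  for (int i = 0; i < seeds0.size(); ++i) {
    R_xlen_t s = seeds0[i];
    if (vol[s] >= tau && !out[s]) { out[s] = true; stack.push_back(s); }
  }
  while (!stack.empty()) {
    R_xlen_t u = stack.back(); stack.pop_back();
    int x, y, z;
    decode(u, nx, ny, x, y, z);
    for (size_t k = 0; k < off.size(); ++k) {
      int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t v = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (!out[v] && vol[v] >= tau) { out[v] = true; stack.push_back(v); }
    }
  }
  return out;
}

// Label connected components of a binary mask (connectivity 6 or 26);
// labels are 1..k in scan order, 0 outside the mask.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3> > off;
  if (connectivity == 6) offsets6(off); else offsets26(off);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t u = stack.back(); stack.pop_back();
      int x, y, z;
      decode(u, nx, ny, x, y, z);
      for (size_t k = 0; k < off.size(); ++k) {
        int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t v = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[v] && lab[v] == 0) { lab[v] = next; stack.push_back(v); }
      }
    }
  }
  return lab;
}

// Directional hole filling: a background voxel becomes object when rays along
// at least `required` of the 26 neighbour directions meet an object voxel
// within `span` unit steps. Sweeps are synchronous; `iterations` sweeps are
// applied sequentially to the updated mask.
// [[Rcpp::export]]
LogicalVector cpp_fill_edge_holes(LogicalVector mask, IntegerVector dim,
                                  int iterations, int span, int required) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<std::array<int,3> > off;
  offsets26(off);
  LogicalVector cur = clone(mask);
  int allow_miss = 26 - required;
  for (int it = 0; it < iterations; ++it) {
    std::vector<R_xlen_t> fills;
    for (R_xlen_t i = 0; i < n; ++i) {
      if (cur[i]) continue;
      int x, y, z;
      decode(i, nx, ny, x, y, z);
      int misses = 0, hits = 0;
      for (int k = 0; k < 26; ++k) {
        bool hit = false;
        int xx = x, yy = y, zz = z;
        for (int s = 1; s <= span; ++s) {
          xx += off[k][0]; yy += off[k][1]; zz += off[k][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            break;
          if (cur[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)]) {
            hit = true;
            break;
          }
        }
        if (hit) ++hits; else { ++misses; if (misses > allow_miss) break; }
      }
      if (hits >= required) fills.push_back(i);
    }
    for (size_t k = 0; k < fills.size(); ++k) cur[fills[k]] = true;
    if (fills.empty()) break;
  }
  return cur;
}

// Mark all voxels within a per-centre radius (voxel units) of each centre.
// `centers0` are 0-based integer voxel coordinates (rows: x, y, z).
// [[Rcpp::export]]
LogicalVector cpp_claim_balls(LogicalVector claimed, IntegerVector dim,
                              IntegerMatrix centers0, NumericVector radii) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out = clone(claimed);
  for (int s = 0; s < centers0.nrow(); ++s) {
    int cx = centers0(s, 0), cy = centers0(s, 1), cz = centers0(s, 2);
    double r = radii[s], r2 = r * r;
    int ir = (int)std::floor(r);
    for (int dz = -ir; dz <= ir; ++dz) {
      int z = cz + dz;
      if (z < 0 || z >= nz) continue;
      for (int dy = -ir; dy <= ir; ++dy) {
        int y = cy + dy;
        if (y < 0 || y >= ny) continue;
        double d2 = (double)dz * dz + (double)dy * dy;
        if (d2 > r2) continue;
        R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        for (int dx = -ir; dx <= ir; ++dx) {
          int x = cx + dx;
          if (x < 0 || x >= nx) continue;
          if (d2 + (double)dx * dx <= r2) out[base + x] = true;
        }
      }
    }
  }
  return out;
}

// Exact 2-D median filter with a k x k window truncated at the image border.
// Median of an even count is the mean of the two central order statistics.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter2d(NumericMatrix img, int k) {
  int nx = img.nrow(), ny = img.ncol();
  int h = k / 2;
  NumericMatrix out(nx, ny);
  std::vector<double> win;
  win.reserve((size_t)k * k);
  for (int y = 0; y < ny; ++y) {
    int y0 = std::max(0, y - h), y1 = std::min(ny - 1, y + h);
    for (int x = 0; x < nx; ++x) {
      int x0 = std::max(0, x - h), x1 = std::min(nx - 1, x + h);
      win.clear();
      for (int yy = y0; yy <= y1; ++yy)
        for (int xx = x0; xx <= x1; ++xx)
          win.push_back(img(xx, yy));
      size_t m = win.size();
      size_t mid = m / 2;
      std::nth_element(win.begin(), win.begin() + mid, win.end());
      double med = win[mid];
      if (m % 2 == 0) {
        double lo = *std::max_element(win.begin(), win.begin() + mid);
        med = 0.5 * (med + lo);
      }
      out(x, y) = med;
    }
  }
  return out;
}

// Cluster 3-D points by single-linkage with link distance <= radius
// (grid-hashed union-find). Returns 1-based cluster labels per point.
// [[Rcpp::export]]
IntegerVector cpp_cluster_points(NumericMatrix pts, double radius) {
  int n = pts.nrow();
  IntegerVector lab(n);
  if (n == 0) return lab;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  double cell = std::max(radius, 1e-9);
  std::unordered_map<long long, std::vector<int> > hash;
  std::vector<long long> key(n);
  for (int i = 0; i < n; ++i) {
    long long cx = (long long)std::floor(pts(i, 0) / cell);
    long long cy = (long long)std::floor(pts(i, 1) / cell);
    long long cz = (long long)std::floor(pts(i, 2) / cell);
    long long k = ((cx + 1048576) << 42) ^ ((cy + 1048576) << 21) ^
                  (cz + 1048576);
    key[i] = k;
    hash[k].push_back(i);
  }
  double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    long long cx = (long long)std::floor(pts(i, 0) / cell);
    long long cy = (long long)std::floor(pts(i, 1) / cell);
    long long cz = (long long)std::floor(pts(i, 2) / cell);
    for (long long dz = -1; dz <= 1; ++dz)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dx = -1; dx <= 1; ++dx) {
          long long k = ((cx + dx + 1048576) << 42) ^
                        ((cy + dy + 1048576) << 21) ^ (cz + dz + 1048576);
          std::unordered_map<long long, std::vector<int> >::iterator it =
              hash.find(k);
          if (it == hash.end()) continue;
          for (size_t q = 0; q < it->second.size(); ++q) {
            int j = it->second[q];
            if (j <= i) continue;
            double ddx = pts(i, 0) - pts(j, 0);
            double ddy = pts(i, 1) - pts(j, 1);
            double ddz = pts(i, 2) - pts(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) {
              int a = find(i), b = find(j);
              if (a != b) parent[b] = a;
            }
          }
        }
  }
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    if (remap.find(r) == remap.end()) remap[r] = ++next;
    lab[i] = remap[r];
  }
  return lab;
}

// For each row of `a`, the minimum Euclidean distance to any row of `b`.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix a, NumericMatrix b) {
  int na = a.nrow(), nb = b.nrow(), d = a.ncol();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double t = a(i, k) - b(j, k);
        s += t * t;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
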
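// Voxel-level primitives for 3D filament analysis.
// Arrays are column-major with dims (nx, ny, nz); linear index = x + nx*(y + ny*z).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const double BIG = 1e20;

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// in voxel units; distance of each foreground voxel to the nearest
// background voxel centre. Background voxels get 0.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0; z[0] = -BIG; z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q; z[k] = s; z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d_sq(LogicalVector fg, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = fg[i] ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along x
  for (int zz = 0; zz < nz; zz++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * zz);
      for (int x = 0; x < nx; x++) f[x] = out[base + x];
      dt1d(f, d, nx, v, z);
      for (int x = 0; x < nx; x++) out[base + x] = d[x];
    }
  // along y
  for (int zz = 0; zz < nz; zz++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * zz;
      for (int y = 0; y < ny; y++) f[y] = out[base + (R_xlen_t)nx * y];
      dt1d(f, d, ny, v, z);
      for (int y = 0; y < ny; y++) out[base + (R_xlen_t)nx * y] = d[y];
    }
  // along z
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int zz = 0; zz < nz; zz++) f[zz] = out[base + stride * zz];
      dt1d(f, d, nz, v, z);
      for (int zz = 0; zz < nz; zz++) out[base + stride * zz] = d[zz];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Separable convolution along one axis, zero padding outside the volume.
// kernel has odd length; centre aligned.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector a, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kn = kernel.size();
  const int kr = (kn - 1) / 2;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  const R_xlen_t stride = (axis == 0) ? 1 :
                          (axis == 1) ? (R_xlen_t)nx : (R_xlen_t)nx * ny;

  std::vector<double> line(len), res(len);
  // iterate over all lines along the chosen axis
  int n1, n2; R_xlen_t s1, s2;
  if (axis == 0)      { n1 = ny; s1 = nx; n2 = nz; s2 = (R_xlen_t)nx * ny; }
  else if (axis == 1) { n1 = nx; s1 = 1;  n2 = nz; s2 = (R_xlen_t)nx * ny; }
  else                { n1 = nx; s1 = 1;  n2 = ny; s2 = (R_xlen_t)nx; }

  for (int j = 0; j < n2; j++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = s1 * i + s2 * j;
      for (int t = 0; t < len; t++) line[t] = a[base + stride * t];
      for (int t = 0; t < len; t++) {
        double acc = 0.0;
        int lo = std::max(0, t - kr), hi = std::min(len - 1, t + kr);
        for (int u = lo; u <= hi; u++) acc += line[u] * kernel[(t - u) + kr];
        res[t] = acc;
      }
      for (int t = 0; t < len; t++) out[base + stride * t] = res[t];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Running box sum along one axis (window = 2*r+1 voxels, zero outside).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_boxsum_axis(NumericVector a, IntegerVector dim, int r, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  const R_xlen_t stride = (axis == 0) ? 1 :
                          (axis == 1) ? (R_xlen_t)nx : (R_xlen_t)nx * ny;
  int n1, n2; R_xlen_t s1, s2;
  if (axis == 0)      { n1 = ny; s1 = nx; n2 = nz; s2 = (R_xlen_t)nx * ny; }
  else if (axis == 1) { n1 = nx; s1 = 1;  n2 = nz; s2 = (R_xlen_t)nx * ny; }
  else                { n1 = nx; s1 = 1;  n2 = ny; s2 = (R_xlen_t)nx; }

  std::vector<double> cum(len + 1);
  for (int j = 0; j < n2; j++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = s1 * i + s2 * j;
      cum[0] = 0.0;
      for (int t = 0; t < len; t++) cum[t + 1] = cum[t] + a[base + stride * t];
      for (int t = 0; t < len; t++) {
        int lo = std::max(0, t - r), hi = std::min(len - 1, t + r);
        out[base + stride * t] = cum[hi + 1] - cum[lo];
      }
    }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (26- or 6-connectivity).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector fg, IntegerVector dim, int conn) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!fg[s] || lab[s]) continue;
    next++;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int x = cur % nx, y = (cur / nx) % ny, zz = cur / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            if (!dx && !dy && !dz) continue;
            if (conn == 6 && (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1)
              continue;
            int x2 = x + dx, y2 = y + dy, z2 = zz + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
              continue;
            R_xlen_t q = x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2);
            if (fg[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
          }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// 26-adjacency edge list among foreground voxels. Voxel ids are 1-based
// positions in the linear-index-sorted list of foreground voxels.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_fg_edges(LogicalVector fg, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> id(n, 0);
  int cnt = 0;
  for (R_xlen_t s = 0; s < n; s++) if (fg[s]) id[s] = ++cnt;
  std::vector<int> ea, eb;
  // only forward offsets to avoid duplicates
  for (R_xlen_t s = 0; s < n; s++) {
    if (!fg[s]) continue;
    int x = s % nx, y = (s / nx) % ny, zz = s / ((R_xlen_t)nx * ny);
    for (int dz = 0; dz <= 1; dz++)
      for (int dy = (dz == 0 ? 0 : -1); dy <= 1; dy++)
        for (int dx = (dz == 0 && dy == 0 ? 1 : -1); dx <= 1; dx++) {
          int x2 = x + dx, y2 = y + dy, z2 = zz + dz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          R_xlen_t q = x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2);
          if (fg[q]) { ea.push_back(id[s]); eb.push_back(id[q]); }
        }
  }
  IntegerMatrix out(ea.size(), 2);
  for (size_t i = 0; i < ea.size(); i++) { out(i, 0) = ea[i]; out(i, 1) = eb[i]; }
  return out;
}

// ---------------------------------------------------------------------------
// Topology-preserving thinning.
//
// A voxel is "simple" iff (a) the foreground restricted to its 26-neighbourhood
// has exactly one 26-connected component and (b) the background restricted to
// its 18-neighbourhood has exactly one 6-connected component that is 6-adjacent
// to the voxel (standard (26,6) characterisation). Removal proceeds in
// ascending distance-transform order, ties broken by linear index (z,y,x
// lexicographic). Endpoints (<= 1 foreground neighbour) are never removed.
// With protect_faces, voxels outside the volume count as foreground, so a
// component can never be detached from the bounding faces.
// ---------------------------------------------------------------------------

static inline int loc_idx(int dx, int dy, int dz) {
  return (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1));
}

// fill 27-voxel occupancy around (x,y,z); outside -> `outside_val`
static void fill_occ(const LogicalVector& fg, int nx, int ny, int nz,
                     int x, int y, int z, bool outside_val, bool occ[27]) {
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        int x2 = x + dx, y2 = y + dy, z2 = z + dz;
        bool v;
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
          v = outside_val;
        else
          v = fg[x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2)];
        occ[loc_idx(dx, dy, dz)] = v;
      }
}

// connectivity condition: foreground in N26 stays in one 26-component
static bool fg_connected_without(const bool occ[27]) {
  bool seen[27] = {false};
  int ncomp_fg = 0;
  for (int p = 0; p < 27; p++) {
    if (p == 13 || !occ[p] || seen[p]) continue;
    ncomp_fg++;
    if (ncomp_fg > 1) return false;
    int stack[27], top = 0;
    stack[top++] = p; seen[p] = true;
    while (top) {
      int cur = stack[--top];
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
            if (x2 < 0 || x2 > 2 || y2 < 0 || y2 > 2 || z2 < 0 || z2 > 2)
              continue;
            int q = x2 + 3 * (y2 + 3 * z2);
            if (q == 13 || q == cur) continue;
            if (occ[q] && !seen[q]) { seen[q] = true; stack[top++] = q; }
          }
    }
  }
  return ncomp_fg == 1;
}

static bool is_simple(const bool occ[27]) {
  // (a) 26-components of foreground in N26
  bool seen[27] = {false};
  int ncomp_fg = 0;
  for (int p = 0; p < 27; p++) {
    if (p == 13 || !occ[p] || seen[p]) continue;
    ncomp_fg++;
    if (ncomp_fg > 1) return false;
    int stack[27], top = 0;
    stack[top++] = p; seen[p] = true;
    while (top) {
      int cur = stack[--top];
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
            if (x2 < 0 || x2 > 2 || y2 < 0 || y2 > 2 || z2 < 0 || z2 > 2)
              continue;
            int q = x2 + 3 * (y2 + 3 * z2);
            if (q == 13 || q == cur) continue;
            if (occ[q] && !seen[q]) { seen[q] = true; stack[top++] = q; }
          }
    }
  }
  if (ncomp_fg != 1) return false;

  // (b) 6-components of background in N18 that touch a face neighbour
  // N18: positions with |dx|+|dy|+|dz| <= 2, excluding centre
  bool inN18[27];
  for (int p = 0; p < 27; p++) {
    int cx = p % 3 - 1, cy = (p / 3) % 3 - 1, cz = p / 9 - 1;
    inN18[p] = (std::abs(cx) + std::abs(cy) + std::abs(cz) <= 2) && p != 13;
  }
  static const int faces[6] = { loc_idx(-1,0,0), loc_idx(1,0,0),
                                loc_idx(0,-1,0), loc_idx(0,1,0),
                                loc_idx(0,0,-1), loc_idx(0,0,1) };
  bool seenb[27] = {false};
  int ncomp_bg = 0;
  for (int fi = 0; fi < 6; fi++) {
    int p = faces[fi];
    if (occ[p] || seenb[p]) continue;
    ncomp_bg++;
    if (ncomp_bg > 1) return false;
    int stack[27], top = 0;
    stack[top++] = p; seenb[p] = true;
    while (top) {
      int cur = stack[--top];
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      static const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; k++) {
        int x2 = cx + d6[k][0], y2 = cy + d6[k][1], z2 = cz + d6[k][2];
        if (x2 < 0 || x2 > 2 || y2 < 0 || y2 > 2 || z2 < 0 || z2 > 2) continue;
        int q = x2 + 3 * (y2 + 3 * z2);
        if (!inN18[q]) continue;
        if (!occ[q] && !seenb[q]) { seenb[q] = true; stack[top++] = q; }
      }
    }
  }
  return ncomp_bg == 1;
}

// [[Rcpp::export]]
bool cpp_is_simple_point(LogicalVector fg, IntegerVector dim,
                         int x, int y, int z, bool protect_faces) {
  bool occ[27];
  fill_occ(fg, dim[0], dim[1], dim[2], x, y, z, protect_faces, occ);
  return is_simple(occ);
}

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector fg_in, NumericVector dt,
                         IntegerVector dim, bool protect_faces,
                         bool connectivity_only) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector fg = clone(fg_in);

  std::vector<R_xlen_t> order;
  for (R_xlen_t s = 0; s < n; s++) if (fg[s]) order.push_back(s);
  std::stable_sort(order.begin(), order.end(),
                   [&dt](R_xlen_t a, R_xlen_t b) { return dt[a] < dt[b]; });

  bool occ[27];
  int pass = 0;
  bool changed = true;
  while (changed && pass < 10000) {
    changed = false;
    pass++;
    for (size_t oi = 0; oi < order.size(); oi++) {
      R_xlen_t s = order[oi];
      if (!fg[s]) continue;
      int x = s % nx, y = (s / nx) % ny, zz = s / ((R_xlen_t)nx * ny);
      fill_occ(fg, nx, ny, nz, x, y, zz, protect_faces, occ);
      int nb = 0;
      for (int p = 0; p < 27; p++) if (p != 13 && occ[p]) nb++;
      if (nb <= 1) continue;  // endpoint or isolated voxel
      bool removable = connectivity_only ? fg_connected_without(occ)
                                         : is_simple(occ);
      if (removable) { fg[s] = false; changed = true; }
    }
  }
  return fg;
}

// ---------------------------------------------------------------------------
// 26-neighbour counts for foreground voxels (0 outside, no virtual padding).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_neighbor_count26(LogicalVector fg, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n, 0);
  for (R_xlen_t s = 0; s < n; s++) {
    if (!fg[s]) continue;
    int x = s % nx, y = (s / nx) % ny, zz = s / ((R_xlen_t)nx * ny);
    int nb = 0;
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          if (!dx && !dy && !dz) continue;
          int x2 = x + dx, y2 = y + dy, z2 = zz + dz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          if (fg[x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2)]) nb++;
        }
    out[s] = nb;
  }
  return out;
}
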
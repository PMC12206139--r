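// Voxel-level kernels: grayscale ball erosion/dilation, 3D connected-component
// labelling, topology-preserving 3D thinning, and soft tube rasterisation.
// Volumes are R arrays with dim = c(nz, ny, nx); z is the fastest index and
// increases with depth.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t lin_index(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// Discrete ball offsets: voxel included iff its physical centre lies within
// `radius` micrometres of the origin under the (dz, dy, dx) spacing.
static void ball_offsets(double radius, const NumericVector& spacing,
                         std::vector<int>& oz, std::vector<int>& oy,
                         std::vector<int>& ox) {
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  const int rz = (int)std::floor(radius / sz);
  const int ry = (int)std::floor(radius / sy);
  const int rx = (int)std::floor(radius / sx);
  const double r2 = radius * radius;
  for (int x = -rx; x <= rx; ++x)
    for (int y = -ry; y <= ry; ++y)
      for (int z = -rz; z <= rz; ++z) {
        const double d2 = z * sz * z * sz + y * sy * y * sy + x * sx * x * sx;
        if (d2 <= r2) { oz.push_back(z); oy.push_back(y); ox.push_back(x); }
      }
}

// [[Rcpp::export]]
NumericVector cpp_ball_filter(NumericVector vol, IntegerVector dim,
                              double radius, NumericVector spacing,
                              bool use_max) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> oz, oy, ox;
  ball_offsets(radius, spacing, oz, oy, ox);
  const int m = (int)oz.size();
  NumericVector out(clone(vol));
  if (m <= 1) return out;
  // bound for the early-exit: nothing can go below (above) the global extreme
  double lim = vol[0];
  for (R_xlen_t i = 1; i < vol.size(); ++i)
    lim = use_max ? std::max(lim, vol[i]) : std::min(lim, vol[i]);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double v = vol[lin_index(z, y, x, nz, ny)];
        for (int k = 0; k < m; ++k) {
          const int zz = z + oz[k], yy = y + oy[k], xx = x + ox[k];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;  // outside the grid imposes no constraint
          const double w = vol[lin_index(zz, yy, xx, nz, ny)];
          if (use_max ? (w > v) : (w < v)) {
            v = w;
            if (v == lim) break;
          }
        }
        out[lin_index(z, y, x, nz, ny)] = v;
      }
  return out;
}

// 26- or 6-connected component labelling by breadth-first search.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector labels(mask.size(), 0);
  std::vector<int> oz, oy, ox;
  for (int x = -1; x <= 1; ++x)
    for (int y = -1; y <= 1; ++y)
      for (int z = -1; z <= 1; ++z) {
        const int s = std::abs(x) + std::abs(y) + std::abs(z);
        if (s == 0) continue;
        if (connectivity == 6 && s != 1) continue;
        oz.push_back(z); oy.push_back(y); ox.push_back(x);
      }
  const int m = (int)oz.size();
  int next = 0;
  std::queue<std::array<int, 3> > q;
  for (int x0 = 0; x0 < nx; ++x0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int z0 = 0; z0 < nz; ++z0) {
        const R_xlen_t i0 = lin_index(z0, y0, x0, nz, ny);
        if (!mask[i0] || labels[i0]) continue;
        ++next;
        labels[i0] = next;
        q.push({z0, y0, x0});
        while (!q.empty()) {
          const std::array<int, 3> p = q.front(); q.pop();
          for (int k = 0; k < m; ++k) {
            const int zz = p[0] + oz[k], yy = p[1] + oy[k], xx = p[2] + ox[k];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            const R_xlen_t j = lin_index(zz, yy, xx, nz, ny);
            if (mask[j] && !labels[j]) { labels[j] = next; q.push({zz, yy, xx}); }
          }
        }
      }
  return labels;
}

// ---- simple-point machinery for 3D thinning --------------------------------
// nb[] holds the 3x3x3 neighbourhood as 27 booleans (index z + 3y + 9x,
// offsets shifted by +1); centre is index 13.

static inline int nb_index(int dz, int dy, int dx) {
  return (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
}

// number of 26-connected foreground components among the 26 neighbours
static int n26_components(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++comps;
    std::queue<int> q; q.push(i); seen[i] = true;
    while (!q.empty()) {
      const int c = q.front(); q.pop();
      const int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            const int zz = cz + dz, yy = cy + dy, xx = cx + dx;
            if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2)
              continue;
            const int j = zz + 3 * yy + 9 * xx;
            if (j == 13 || j == c || !nb[j] || seen[j]) continue;
            seen[j] = true; q.push(j);
          }
    }
  }
  return comps;
}

// number of 6-connected background components within the 18-neighbourhood
// that touch a face neighbour of the centre
static int n6_background_components(const bool nb[27]) {
  bool in18[27] = {false};
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        const int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 1 || s == 2) in18[nb_index(dz, dy, dx)] = true;
      }
  bool seen[27] = {false};
  int comps = 0;
  for (int i = 0; i < 27; ++i) {
    if (!in18[i] || nb[i] || seen[i]) continue;
    // grow the 6-connected background component within N18
    std::queue<int> q; q.push(i); seen[i] = true;
    bool touches_face = false;
    while (!q.empty()) {
      const int c = q.front(); q.pop();
      const int cz = c % 3 - 1, cy = (c / 3) % 3 - 1, cx = c / 9 - 1;
      if (std::abs(cz) + std::abs(cy) + std::abs(cx) == 1) touches_face = true;
      const int step[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        const int zz = cz + step[k][0], yy = cy + step[k][1], xx = cx + step[k][2];
        if (zz < -1 || zz > 1 || yy < -1 || yy > 1 || xx < -1 || xx > 1) continue;
        const int j = nb_index(zz, yy, xx);
        if (!in18[j] || nb[j] || seen[j]) continue;
        seen[j] = true; q.push(j);
      }
    }
    if (touches_face) ++comps;
  }
  return comps;
}

static void fill_neighbourhood(const LogicalVector& mask, int z, int y, int x,
                               int nz, int ny, int nx, bool nb[27]) {
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        const int zz = z + dz, yy = y + dy, xx = x + dx;
        bool v = false;
        if (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
          v = mask[lin_index(zz, yy, xx, nz, ny)];
        nb[nb_index(dz, dy, dx)] = v;
      }
}

static inline int count_fg_neighbours(const bool nb[27]) {
  int n = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++n;
  return n;
}

static inline bool is_simple(const bool nb[27]) {
  return n26_components(nb) == 1 && n6_background_components(nb) == 1;
}

// Curve thinning: sequential deletion of simple, non-endpoint border points,
// cycling through the six face directions until stable. Preserves the number
// of 26-connected components and holes (simple-point criterion) and keeps
// curve endpoints, so elongated structures reduce to one-voxel-wide paths.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  LogicalVector cur(clone(mask));
  const int dirs[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  bool nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      // collect border candidates for this direction
      std::vector<std::array<int, 3> > cand;
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int z = 0; z < nz; ++z) {
            if (!cur[lin_index(z, y, x, nz, ny)]) continue;
            const int zz = z + dirs[d][0], yy = y + dirs[d][1], xx = x + dirs[d][2];
            bool bg = true;
            if (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
              bg = !cur[lin_index(zz, yy, xx, nz, ny)];
            if (bg) cand.push_back({z, y, x});
          }
      for (size_t k = 0; k < cand.size(); ++k) {
        const int z = cand[k][0], y = cand[k][1], x = cand[k][2];
        const R_xlen_t i = lin_index(z, y, x, nz, ny);
        if (!cur[i]) continue;
        fill_neighbourhood(cur, z, y, x, nz, ny, nx, nb);
        const int nfg = count_fg_neighbours(nb);
        if (nfg <= 1) continue;           // endpoint or isolated voxel
        if (!is_simple(nb)) continue;
        cur[i] = false;                    // sequential: later tests see this
        changed = true;
      }
    }
  }
  return cur;
}

// Soft (partial-volume) rasterisation of tube centrelines: for each centreline
// sample point (physical z, y, x in micrometres) stamp a ball of the given
// radius with a one-voxel linear edge ramp, max-blended into `field`.
// [[Rcpp::export]]
NumericVector cpp_stamp_tubes(NumericVector field, IntegerVector dim,
                              NumericVector spacing, NumericMatrix pts,
                              NumericVector radius) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  const double h = std::min(sz, std::min(sy, sx));
  NumericVector out(clone(field));
  for (int p = 0; p < pts.nrow(); ++p) {
    const double pz = pts(p, 0), py = pts(p, 1), px = pts(p, 2);
    const double r = radius[p];
    const double reach = r + h;
    const int z0 = std::max(0, (int)std::ceil((pz - reach) / sz));
    const int z1 = std::min(nz - 1, (int)std::floor((pz + reach) / sz));
    const int y0 = std::max(0, (int)std::ceil((py - reach) / sy));
    const int y1 = std::min(ny - 1, (int)std::floor((py + reach) / sy));
    const int x0 = std::max(0, (int)std::ceil((px - reach) / sx));
    const int x1 = std::min(nx - 1, (int)std::floor((px + reach) / sx));
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int z = z0; z <= z1; ++z) {
          const double dz = z * sz - pz, dy = y * sy - py, dx = x * sx - px;
          const double d = std::sqrt(dz * dz + dy * dy + dx * dx);
          double v = (r - d) / h + 0.5;   // 1 inside, 0 outside, linear ramp
          if (v <= 0) continue;
          if (v > 1) v = 1;
          const R_xlen_t i = lin_index(z, y, x, nz, ny);
          if (v > out[i]) out[i] = v;
        }
  }
  return out;
}
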
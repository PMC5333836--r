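#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// 3D voxel utilities shared by the segmentation module: ball-element
// morphology, 26/6-connected labeling, topology-preserving thinning and
// surface detection. Volumes are passed as flat logical vectors with a dim
// attribute (column-major, as R stores arrays): index = x + nx*(y + ny*z).

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

static std::vector<std::array<int,3>> ball_offsets(double radius) {
  std::vector<std::array<int,3>> off;
  int r = (int)std::floor(radius + 1e-9);
  double r2 = radius * radius + 1e-9;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dx*dx + dy*dy + dz*dz <= r2)
          off.push_back({dx, dy, dz});
  return off;
}

// [[Rcpp::export]]
LogicalVector cpp_ball_dilate(LogicalVector mask, IntegerVector dim, double radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size(), false);
  std::vector<std::array<int,3>> off = ball_offsets(radius);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!mask[idx3(x, y, z, nx, ny)]) continue;
        for (auto &o : off) {
          int xx = x + o[0], yy = y + o[1], zz = z + o[2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
          out[idx3(xx, yy, zz, nx, ny)] = true;
        }
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_ball_erode(LogicalVector mask, IntegerVector dim, double radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size(), false);
  std::vector<std::array<int,3>> off = ball_offsets(radius);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!mask[idx3(x, y, z, nx, ny)]) continue;
        bool keep = true;
        for (auto &o : off) {
          int xx = x + o[0], yy = y + o[1], zz = z + o[2];
          // out-of-bounds counts as background
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz ||
              !mask[idx3(xx, yy, zz, nx, ny)]) { keep = false; break; }
        }
        if (keep) out[idx3(x, y, z, nx, ny)] = true;
      }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.clear();
    stack.push_back((int)s);
    lab[s] = next;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int z = cur / (nx * ny), rem = cur % (nx * ny);
      int y = rem / nx, x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
            int ni = idx3(xx, yy, zz, nx, ny);
            if (mask[ni] && !lab[ni]) { lab[ni] = next; stack.push_back(ni); }
          }
    }
  }
  return lab;
}

// [[Rcpp::export]]
LogicalVector cpp_surface_voxels(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size(), false);
  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!mask[i]) continue;
        for (auto &d : d6) {
          int xx = x + d[0], yy = y + d[1], zz = z + d[2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz ||
              !mask[idx3(xx, yy, zz, nx, ny)]) { out[i] = true; break; }
        }
      }
  return out;
}

// --- (26,6) simple-point machinery -----------------------------------------
// nb[] holds the 3x3x3 neighborhood as booleans (foreground), linear index
// k = (dx+1) + 3*(dy+1) + 9*(dz+1); center k = 13.

static inline int nb_index(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// number of 26-connected foreground components among the 26 neighbors
static int n26_components(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int k = 0; k < 27; ++k) {
    if (k == 13 || !nb[k] || seen[k]) continue;
    ++comps;
    std::vector<int> st{k};
    seen[k] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cz = c / 9, cy = (c % 9) / 3, cx = c % 3;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = cx + dx, yy = cy + dy, zz = cz + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2) continue;
            int nk = xx + 3 * yy + 9 * zz;
            if (nk == 13 || nk == c || !nb[nk] || seen[nk]) continue;
            seen[nk] = true;
            st.push_back(nk);
          }
    }
  }
  return comps;
}

// number of 6-connected background components within the 18-neighborhood
// that touch a face neighbor of the center
static int n6_bg_components(const bool nb[27]) {
  auto in18 = [](int k) {
    int dz = k / 9 - 1, dy = (k % 9) / 3 - 1, dx = k % 3 - 1;
    int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
    return s >= 1 && s <= 2;
  };
  auto isface = [](int k) {
    int dz = k / 9 - 1, dy = (k % 9) / 3 - 1, dx = k % 3 - 1;
    return std::abs(dx) + std::abs(dy) + std::abs(dz) == 1;
  };
  bool seen[27] = {false};
  int comps = 0;
  for (int k = 0; k < 27; ++k) {
    if (!isface(k) || nb[k] || seen[k]) continue;  // seed only at face neighbors
    ++comps;
    std::vector<int> st{k};
    seen[k] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cz = c / 9, cy = (c % 9) / 3, cx = c % 3;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (auto &d : d6) {
        int xx = cx + d[0], yy = cy + d[1], zz = cz + d[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2) continue;
        int nk = xx + 3 * yy + 9 * zz;
        if (nk == 13 || nb[nk] || seen[nk] || !in18(nk)) continue;
        seen[nk] = true;
        st.push_back(nk);
      }
    }
  }
  return comps;
}

static void fill_neighborhood(const std::vector<char> &m, int x, int y, int z,
                              int nx, int ny, int nz, bool nb[27]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        bool v = !(xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) &&
                 m[idx3(xx, yy, zz, nx, ny)];
        nb[nb_index(dx, dy, dz)] = v;
      }
}

static inline int count_fg_neighbors(const bool nb[27]) {
  int c = 0;
  for (int k = 0; k < 27; ++k) if (k != 13 && nb[k]) ++c;
  return c;
}

static inline bool is_simple(const bool nb[27]) {
  return n26_components(nb) == 1 && n6_bg_components(nb) == 1;
}

// Sequential 3D thinning with six directional sub-iterations per pass.
// A voxel is deleted only if, at the moment of deletion, it is a border
// voxel in the current direction, simple in the (26,6) sense, and not a
// curve endpoint (>1 foreground 26-neighbor). Sequential re-checking makes
// every deletion topology-preserving; endpoint preservation retains branch
// tips so the result is a curve skeleton. Like other thinning schemes of
// this class, a perfectly axis-aligned tube of exactly even voxel width is
// a degenerate input whose free end can retract.
// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<char> m(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) m[i] = mask[i] ? 1 : 0;
  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  bool nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (auto &d : dirs) {
      // collect candidates with a background neighbor in direction d
      std::vector<int> cand;
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            int i = idx3(x, y, z, nx, ny);
            if (!m[i]) continue;
            int xx = x + d[0], yy = y + d[1], zz = z + d[2];
            bool bg = (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) ||
                      !m[idx3(xx, yy, zz, nx, ny)];
            if (!bg) continue;
            fill_neighborhood(m, x, y, z, nx, ny, nz, nb);
            if (count_fg_neighbors(nb) <= 1) continue;  // endpoint
            if (is_simple(nb)) cand.push_back(i);
          }
      for (int i : cand) {
        int z = i / (nx * ny), rem = i % (nx * ny);
        int y = rem / nx, x = rem % nx;
        fill_neighborhood(m, x, y, z, nx, ny, nz, nb);
        if (count_fg_neighbors(nb) <= 1) continue;
        if (!is_simple(nb)) continue;
        m[i] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = m[i] != 0;
  return out;
}
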
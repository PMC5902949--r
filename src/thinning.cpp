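#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D topological thinning to a unit-wide curve skeleton.
//
// Iteratively deletes simple border points (deletion preserves both the
// number of foreground 26-components and background 6-components, checked
// on the local 3x3x3 neighborhood with the standard two-condition
// characterization) that are not curve endpoints, sweeping the six face
// directions in turn.  Each directional sweep is split into the eight
// 2x2x2 parity subfields: voxels of one subfield are pairwise non-adjacent,
// so deleting them together is equivalent to a parallel deletion and a
// two-voxel-wide rod cannot unravel along its length within a sweep (which
// would erode even-width structures down to a point).

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// foreground value with out-of-volume = background
static inline int fg(const std::vector<unsigned char> &v, int x, int y, int z,
                     int nx, int ny, int nz) {
  if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0;
  return v[idx3(x, y, z, nx, ny)];
}

// Condition 1: exactly one 26-connected foreground component in N26(p).
// Condition 2: exactly one 6-connected background component in N18(p) that
// is 6-adjacent to p.
static bool is_simple(const std::vector<unsigned char> &v, int x, int y, int z,
                      int nx, int ny, int nz) {
  int val[27];
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k)
        val[k] = fg(v, x + dx, y + dy, z + dz, nx, ny, nz);
  // positions: k = (dx+1) + 3*(dy+1) + 9*(dz+1); center k = 13
  // ---- foreground 26-components over N26 ----
  int labels[27];
  for (int i = 0; i < 27; ++i) labels[i] = -1;
  int ncomp_fg = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !val[i] || labels[i] >= 0) continue;
    // BFS
    ++ncomp_fg;
    std::vector<int> stack;
    stack.push_back(i);
    labels[i] = ncomp_fg;
    while (!stack.empty()) {
      int a = stack.back(); stack.pop_back();
      int ax = a % 3, ay = (a / 3) % 3, az = a / 9;
      for (int b = 0; b < 27; ++b) {
        if (b == 13 || !val[b] || labels[b] >= 0) continue;
        int bx = b % 3, by = (b / 3) % 3, bz = b / 9;
        if (std::abs(ax - bx) <= 1 && std::abs(ay - by) <= 1 &&
            std::abs(az - bz) <= 1) {
          labels[b] = ncomp_fg;
          stack.push_back(b);
        }
      }
    }
  }
  if (ncomp_fg != 1) return false;
  // ---- background 6-components in N18, 6-adjacent to center ----
  // N18 = positions with Chebyshev distance 1 excluding the 8 corners
  bool in18[27];
  for (int i = 0; i < 27; ++i) {
    int ix = i % 3 - 1, iy = (i / 3) % 3 - 1, iz = i / 9 - 1;
    int manh = std::abs(ix) + std::abs(iy) + std::abs(iz);
    in18[i] = (i != 13) && (manh <= 2);
  }
  int blab[27];
  for (int i = 0; i < 27; ++i) blab[i] = -1;
  int ncomp_bg = 0;
  for (int i = 0; i < 27; ++i) {
    if (!in18[i] || val[i] || blab[i] >= 0) continue;
    // only count components that touch a face neighbor of the center
    ++ncomp_bg;
    std::vector<int> stack;
    stack.push_back(i);
    blab[i] = ncomp_bg;
    bool touches = false;
    while (!stack.empty()) {
      int a = stack.back(); stack.pop_back();
      int ax = a % 3 - 1, ay = (a / 3) % 3 - 1, az = a / 9 - 1;
      if (std::abs(ax) + std::abs(ay) + std::abs(az) == 1) touches = true;
      for (int b = 0; b < 27; ++b) {
        if (!in18[b] || val[b] || blab[b] >= 0) continue;
        int bx = b % 3 - 1, by = (b / 3) % 3 - 1, bz = b / 9 - 1;
        int d = std::abs(ax - bx) + std::abs(ay - by) + std::abs(az - bz);
        if (d == 1) { blab[b] = ncomp_bg; stack.push_back(b); }
      }
    }
    if (!touches) --ncomp_bg;   // component not 6-adjacent to p: ignore
  }
  return ncomp_bg == 1;
}

static int count_neighbors(const std::vector<unsigned char> &v, int x, int y,
                           int z, int nx, int ny, int nz) {
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        n += fg(v, x + dx, y + dy, z + dz, nx, ny, nz);
      }
  return n;
}

// delete simple, non-endpoint border points until no change
static void thin_to_convergence(std::vector<unsigned char> &v, int nx, int ny,
                                int nz) {
  const int dir[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                         {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      for (int sf = 0; sf < 8; ++sf) {
        const int px = sf & 1, py = (sf >> 1) & 1, pz = (sf >> 2) & 1;
        std::vector<int> cand;
        for (int z = pz; z < nz; z += 2)
          for (int y = py; y < ny; y += 2)
            for (int x = px; x < nx; x += 2) {
              const int i = idx3(x, y, z, nx, ny);
              if (!v[i]) continue;
              if (fg(v, x + dir[d][0], y + dir[d][1], z + dir[d][2],
                     nx, ny, nz))
                continue;                         // not a border point (this dir)
              if (count_neighbors(v, x, y, z, nx, ny, nz) <= 1)
                continue;                         // curve endpoint
              if (is_simple(v, x, y, z, nx, ny, nz)) cand.push_back(i);
            }
        // same-subfield voxels are never 26-adjacent, so these deletions
        // do not interact and need no recheck
        for (size_t c = 0; c < cand.size(); ++c) {
          v[cand[c]] = 0;
          changed = true;
        }
      }
    }
  }
}

// [[Rcpp::export]]
LogicalVector thin_skeleton_cpp(LogicalVector vol, IntegerVector dims,
                                int prune_iters = 3) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<unsigned char> v(n);
  for (int i = 0; i < n; ++i) v[i] = vol[i] ? 1 : 0;
  thin_to_convergence(v, nx, ny, nz);
  // Spur pruning: parallel erosion fronts leave short side branches whose
  // tips the endpoint condition froze; delete curve endpoints (exactly one
  // neighbor) and re-thin, prune_iters times, removing branches shorter
  // than prune_iters voxels (genuine tips lose at most prune_iters voxels).
  // Re-thinning after each prune pass matters: removing a spur can expose
  // voxels that are simple again.
  for (int p = 0; p < prune_iters; ++p) {
    std::vector<int> tips;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int i = idx3(x, y, z, nx, ny);
          if (v[i] && count_neighbors(v, x, y, z, nx, ny, nz) == 1)
            tips.push_back(i);
        }
    bool pruned = false;
    for (size_t c = 0; c < tips.size(); ++c) {
      const int i = tips[c];
      const int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
      // recheck: if this tip's only neighbor was itself pruned first, keep
      // the voxel so a 2-voxel component is not annihilated
      if (count_neighbors(v, x, y, z, nx, ny, nz) == 1) {
        v[i] = 0;
        pruned = true;
      }
    }
    if (pruned) thin_to_convergence(v, nx, ny, nz);
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = v[i] != 0;
  out.attr("dim") = dims;
  return out;
}
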
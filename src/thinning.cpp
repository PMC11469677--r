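// 3D binary thinning and component labeling on voxel lattices.
//
// Thinning removes simple border points (Bertrand's characterization for the
// (26, 6) adjacency pair) in six directional subiterations per pass, with
// sequential re-checking inside each subiteration so the result is
// deterministic and connectivity-preserving. Endpoints (voxels with a single
// object neighbor) are never removed, so open curves keep their tips.

#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

namespace {

// Neighborhood cell index for offset (dx, dy, dz) in {-1,0,1}^3.
inline int ncell(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// Fill the 27-cell object mask around voxel (x, y, z); outside = background.
inline void neighborhood(const std::vector<unsigned char>& img,
                         int d1, int d2, int d3,
                         int x, int y, int z, unsigned char* nb) {
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        bool in = xx >= 0 && xx < d1 && yy >= 0 && yy < d2 && zz >= 0 && zz < d3;
        nb[ncell(dx, dy, dz)] = in ?
          img[(size_t)xx + (size_t)d1 * (yy + (size_t)d2 * zz)] : 0;
        ++k;
      }
}

inline int n_object_neighbors(const unsigned char* nb) {
  int n = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++n;
  return n;
}

// Exactly one 26-connected component of object voxels in N26.
bool one_object_component(const unsigned char* nb) {
  int cx[27], cy[27], cz[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int i = ncell(dx, dy, dz);
        cx[i] = dx; cy[i] = dy; cz[i] = dz;
      }
  bool seen[27] = {false};
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++ncomp;
    if (ncomp > 1) return false;
    std::queue<int> q;
    q.push(s); seen[s] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || t == c || !nb[t] || seen[t]) continue;
        if (std::abs(cx[t] - cx[c]) <= 1 && std::abs(cy[t] - cy[c]) <= 1 &&
            std::abs(cz[t] - cz[c]) <= 1) {
          seen[t] = true; q.push(t);
        }
      }
    }
  }
  return ncomp == 1;
}

// Exactly one 6-connected component of background voxels within N18 that is
// 6-adjacent to the center (flood from the six face neighbors).
bool one_background_component(const unsigned char* nb) {
  int cx[27], cy[27], cz[27];
  bool in18[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int i = ncell(dx, dy, dz);
        cx[i] = dx; cy[i] = dy; cz[i] = dz;
        int nz = (dx != 0) + (dy != 0) + (dz != 0);
        in18[i] = (nz >= 1 && nz <= 2);
      }
  const int faces[6] = {ncell(-1, 0, 0), ncell(1, 0, 0), ncell(0, -1, 0),
                        ncell(0, 1, 0),  ncell(0, 0, -1), ncell(0, 0, 1)};
  bool seen[27] = {false};
  int ncomp = 0;
  for (int f = 0; f < 6; ++f) {
    int s = faces[f];
    if (nb[s] || seen[s]) continue;
    ++ncomp;
    if (ncomp > 1) return false;
    std::queue<int> q;
    q.push(s); seen[s] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || t == c || !in18[t] || nb[t] || seen[t]) continue;
        if (std::abs(cx[t] - cx[c]) + std::abs(cy[t] - cy[c]) +
            std::abs(cz[t] - cz[c]) == 1) {
          seen[t] = true; q.push(t);
        }
      }
    }
  }
  return ncomp == 1;
}

inline bool is_simple(const unsigned char* nb) {
  return one_object_component(nb) && one_background_component(nb);
}

} // namespace

// [[Rcpp::export(name = ".skeletonize3d_cpp")]]
LogicalVector skeletonize3d_cpp(LogicalVector mask) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const size_t n = (size_t)d1 * d2 * d3;
  std::vector<unsigned char> img(n);
  for (size_t i = 0; i < n; ++i) img[i] = (mask[i] == TRUE) ? 1 : 0;

  const int dir[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                         {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  unsigned char nb[27];
  std::vector<size_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < d3; ++z)
        for (int y = 0; y < d2; ++y)
          for (int x = 0; x < d1; ++x) {
            size_t p = (size_t)x + (size_t)d1 * (y + (size_t)d2 * z);
            if (!img[p]) continue;
            int xx = x + dir[d][0], yy = y + dir[d][1], zz = z + dir[d][2];
            bool bg = !(xx >= 0 && xx < d1 && yy >= 0 && yy < d2 &&
                        zz >= 0 && zz < d3) ||
                      !img[(size_t)xx + (size_t)d1 * (yy + (size_t)d2 * zz)];
            if (!bg) continue;
            neighborhood(img, d1, d2, d3, x, y, z, nb);
            if (n_object_neighbors(nb) >= 2 && is_simple(nb))
              cand.push_back(p);
          }
      for (size_t k = 0; k < cand.size(); ++k) {
        size_t p = cand[k];
        int x = (int)(p % d1);
        int y = (int)((p / d1) % d2);
        int z = (int)(p / ((size_t)d1 * d2));
        neighborhood(img, d1, d2, d3, x, y, z, nb);
        if (n_object_neighbors(nb) >= 2 && is_simple(nb)) {
          img[p] = 0;
          changed = true;
        }
      }
    }
  }

  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = img[i] ? TRUE : FALSE;
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export(name = ".label_components26_cpp")]]
IntegerVector label_components26_cpp(LogicalVector mask) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const size_t n = (size_t)d1 * d2 * d3;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<size_t> q;
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x) {
        size_t p = (size_t)x + (size_t)d1 * (y + (size_t)d2 * z);
        if (mask[p] != TRUE || lab[p] != 0) continue;
        lab[p] = ++next;
        q.push(p);
        while (!q.empty()) {
          size_t c = q.front(); q.pop();
          int cx = (int)(c % d1);
          int cy = (int)((c / d1) % d2);
          int cz = (int)(c / ((size_t)d1 * d2));
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                int xx = cx + dx, yy = cy + dy, zz = cz + dz;
                if (xx < 0 || xx >= d1 || yy < 0 || yy >= d2 ||
                    zz < 0 || zz >= d3) continue;
                size_t t = (size_t)xx + (size_t)d1 * (yy + (size_t)d2 * zz);
                if (mask[t] == TRUE && lab[t] == 0) {
                  lab[t] = next;
                  q.push(t);
                }
              }
        }
      }
  lab.attr("dim") = dims;
  return lab;
}
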
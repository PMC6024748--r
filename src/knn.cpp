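#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Radius-capped k-nearest-neighbour edges via a uniform grid with cell
// side = radius_cap, so candidate neighbours live in the 27 surrounding
// cells. Returns directed edges (i -> each of its k nearest within the
// cap); the caller symmetrizes.

static inline int64_t cell_key(int cx, int cy, int cz) {
  // pack three 21-bit signed-offset indices
  return ((int64_t)(cx + 1048576) << 42) |
         ((int64_t)(cy + 1048576) << 21) |
         (int64_t)(cz + 1048576);
}

// [[Rcpp::export(name = ".knn_edges_cpp")]]
List knn_edges_cpp(NumericMatrix pts, int k, double radius_cap) {
  const int n = pts.nrow();
  const double r2 = radius_cap * radius_cap;
  std::unordered_map<int64_t, std::vector<int> > grid;
  grid.reserve(n * 2);
  std::vector<int> cxs(n), cys(n), czs(n);
  for (int i = 0; i < n; ++i) {
    int cx = (int)std::floor(pts(i, 0) / radius_cap);
    int cy = (int)std::floor(pts(i, 1) / radius_cap);
    int cz = (int)std::floor(pts(i, 2) / radius_cap);
    cxs[i] = cx; cys[i] = cy; czs[i] = cz;
    grid[cell_key(cx, cy, cz)].push_back(i);
  }
  std::vector<int> ei, ej;
  std::vector<double> ew;
  ei.reserve((size_t)n * k); ej.reserve((size_t)n * k);
  ew.reserve((size_t)n * k);
  std::vector<std::pair<double, int> > cand;
  for (int i = 0; i < n; ++i) {
    cand.clear();
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(cell_key(cxs[i] + dx, cys[i] + dy, czs[i] + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j == i) continue;
            double ddx = pts(i, 0) - pts(j, 0);
            double ddy = pts(i, 1) - pts(j, 1);
            double ddz = pts(i, 2) - pts(j, 2);
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 <= r2) cand.push_back(std::make_pair(d2, j));
          }
        }
    size_t kk = std::min((size_t)k, cand.size());
    if (kk == 0) continue;
    std::partial_sort(cand.begin(), cand.begin() + kk, cand.end());
    for (size_t m = 0; m < kk; ++m) {
      ei.push_back(i + 1);
      ej.push_back(cand[m].second + 1);
      ew.push_back(std::sqrt(cand[m].first));
    }
  }
  return List::create(_["i"] = wrap(ei), _["j"] = wrap(ej),
                      _["w"] = wrap(ew));
}
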
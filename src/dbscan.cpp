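#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Grid-indexed DBSCAN on 2D points (Euclidean metric).
//
// Semantics (pinned for reproducibility):
//  * core point: >= minPts points within distance eps, the point itself included;
//  * clusters are discovered by scanning points in ascending row index, so cluster
//    ids follow discovery order;
//  * a border point reachable from several clusters keeps the label of the cluster
//    discovered first;
//  * label 0 marks noise.
//
// The eps-neighborhood query hashes points into a uniform grid of cell width eps;
// only the 3x3 cell neighborhood needs to be scanned.

static inline int64_t cell_key(int ix, int iy) {
  return (static_cast<int64_t>(ix) << 32) ^ (static_cast<uint32_t>(iy));
}

// [[Rcpp::export(name = ".dbscan_cpp")]]
IntegerVector dbscan_cpp(NumericVector x, NumericVector y, double eps, int minPts) {
  const int n = x.size();
  IntegerVector labels(n, NA_INTEGER);  // NA = unvisited, 0 = noise, >0 = cluster
  if (n == 0) return labels;

  const double eps2 = eps * eps;
  std::unordered_map<int64_t, std::vector<int> > grid;
  grid.reserve(n * 2);
  std::vector<int> ix(n), iy(n);
  for (int i = 0; i < n; ++i) {
    ix[i] = static_cast<int>(std::floor(x[i] / eps));
    iy[i] = static_cast<int>(std::floor(y[i] / eps));
    grid[cell_key(ix[i], iy[i])].push_back(i);
  }

  std::vector<int> nb;
  nb.reserve(64);
  auto region_query = [&](int i) {
    nb.clear();
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        auto it = grid.find(cell_key(ix[i] + dx, iy[i] + dy));
        if (it == grid.end()) continue;
        for (int j : it->second) {
          double ddx = x[j] - x[i], ddy = y[j] - y[i];
          if (ddx * ddx + ddy * ddy <= eps2) nb.push_back(j);
        }
      }
    }
    std::sort(nb.begin(), nb.end());
  };

  int cid = 0;
  std::queue<int> seeds;
  for (int i = 0; i < n; ++i) {
    if (!IntegerVector::is_na(labels[i])) continue;
    region_query(i);
    if (static_cast<int>(nb.size()) < minPts) {
      labels[i] = 0;  // noise (may be relabelled as border later)
      continue;
    }
    ++cid;
    labels[i] = cid;
    for (int j : nb) {
      if (j != i) seeds.push(j);
    }
    while (!seeds.empty()) {
      int q = seeds.front();
      seeds.pop();
      if (labels[q] == 0) labels[q] = cid;               // border point
      if (!IntegerVector::is_na(labels[q])) continue;    // already claimed
      labels[q] = cid;
      region_query(q);
      if (static_cast<int>(nb.size()) >= minPts) {
        for (int j : nb) {
          if (IntegerVector::is_na(labels[j]) || labels[j] == 0) seeds.push(j);
        }
      }
    }
  }
  return labels;
}
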
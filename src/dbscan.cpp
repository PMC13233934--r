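// Density-based clustering (DBSCAN) on 3D point clouds, with a uniform-grid
// spatial hash for neighbor queries.  Used on (x, y, time_scale * t)
// pseudo-spike events; torus handling is done by the caller via the
// shift-and-merge scheme, so the metric here is plain Euclidean.
//
// Conventions match the common reference implementation: a point's
// eps-neighborhood includes the point itself, and a point is a core point if
// that neighborhood holds at least min_samples points.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericMatrix pts, double eps, int min_samples) {
  const int n = pts.nrow();
  IntegerVector labels(n, 0); // 0 = unvisited, -1 = noise, >0 = cluster id
  if (n == 0) return labels;

  const double *x = &pts(0, 0), *y = &pts(0, 1), *z = &pts(0, 2);
  const double eps2 = eps * eps;

  // grid hash with cell edge = eps
  std::vector<long long> cx(n), cy(n), cz(n);
  long long minx = 0, miny = 0, minz = 0;
  for (int i = 0; i < n; ++i) {
    cx[i] = (long long)std::floor(x[i] / eps);
    cy[i] = (long long)std::floor(y[i] / eps);
    cz[i] = (long long)std::floor(z[i] / eps);
    if (i == 0 || cx[i] < minx) minx = cx[i];
    if (i == 0 || cy[i] < miny) miny = cy[i];
    if (i == 0 || cz[i] < minz) minz = cz[i];
  }
  long long spanx = 0, spany = 0;
  for (int i = 0; i < n; ++i) {
    cx[i] -= minx; cy[i] -= miny; cz[i] -= minz;
    if (cx[i] > spanx) spanx = cx[i];
    if (cy[i] > spany) spany = cy[i];
  }
  const long long mx = spanx + 3, my = spany + 3;
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(n * 2);
  for (int i = 0; i < n; ++i)
    grid[(cz[i] * my + cy[i]) * mx + cx[i]].push_back(i);

  std::vector<int> neigh;
  neigh.reserve(256);
  auto region_query = [&](int i) {
    neigh.clear();
    for (long long dz = -1; dz <= 1; ++dz)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dx = -1; dx <= 1; ++dx) {
          long long key = ((cz[i] + dz) * my + (cy[i] + dy)) * mx + (cx[i] + dx);
          auto it = grid.find(key);
          if (it == grid.end()) continue;
          for (int j : it->second) {
            double ddx = x[i] - x[j], ddy = y[i] - y[j], ddz = z[i] - z[j];
            if (ddx * ddx + ddy * ddy + ddz * ddz <= eps2) neigh.push_back(j);
          }
        }
  };

  int cluster = 0;
  std::queue<int> seeds;
  for (int i = 0; i < n; ++i) {
    if (labels[i] != 0) continue;
    region_query(i);
    if ((int)neigh.size() < min_samples) { labels[i] = -1; continue; }
    ++cluster;
    labels[i] = cluster;
    for (int j : neigh) if (labels[j] <= 0) { if (labels[j] == 0) seeds.push(j); labels[j] = cluster; }
    while (!seeds.empty()) {
      int j = seeds.front(); seeds.pop();
      region_query(j);
      if ((int)neigh.size() < min_samples) continue;
      for (int k : neigh) {
        if (labels[k] > 0) continue;
        if (labels[k] == 0) seeds.push(k);
        labels[k] = cluster;
      }
    }
  }
  for (int i = 0; i < n; ++i) if (labels[i] < 0) labels[i] = 0;
  return labels;
}

// Maximum pairwise minimal-image (toroidal) distance between 2D points.
// [[Rcpp::export]]
double cpp_max_pairwise_toroidal(NumericMatrix xy, double nrows) {
  const int n = xy.nrow();
  double best2 = 0.0;
  const double half = nrows / 2.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = std::fabs(xy(i, 0) - xy(j, 0));
      double dy = std::fabs(xy(i, 1) - xy(j, 1));
      if (dx > half) dx = nrows - dx;
      if (dy > half) dy = nrows - dy;
      double d2 = dx * dx + dy * dy;
      if (d2 > best2) best2 = d2;
    }
  }
  return std::sqrt(best2);
}
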
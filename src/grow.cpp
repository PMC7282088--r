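#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static void neighborOffsets(int connectivity, std::vector<int>& dxs,
                            std::vector<int>& dys, std::vector<int>& dzs) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int ord = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (ord == 0) continue;
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
}

// Connected component of the seed voxel within {values > threshold},
// depth-first on a 3D grid. `seed` is a 1-based linear index into the
// array laid out with dim = (nx, ny, nz) in column-major order.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (full neighborhood).
// [[Rcpp::export(name = ".cc_from_seed")]]
LogicalVector cc_from_seed(NumericVector values, IntegerVector dim,
                           int seed, double threshold, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (values.size() != n) stop("values length does not match dim");
  if (seed < 1 || seed > n) stop("seed out of bounds");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  LogicalVector comp(n, false);
  const int s = seed - 1;
  if (!(values[s] > threshold)) return comp;

  std::vector<int> dxs, dys, dzs;
  neighborOffsets(connectivity, dxs, dys, dzs);

  std::vector<int> stack;
  stack.reserve(256);
  comp[s] = true;
  stack.push_back(s);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
    for (size_t k = 0; k < dxs.size(); ++k) {
      int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      int w = xx + nx * (yy + ny * zz);
      if (!comp[w] && values[w] > threshold) {
        comp[w] = true;
        stack.push_back(w);
      }
    }
  }
  return comp;
}

struct DSU {
  std::vector<int> parent, size, cntSlice, cntInter;
  int find(int v) {
    while (parent[v] != v) {
      parent[v] = parent[parent[v]];
      v = parent[v];
    }
    return v;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
    cntSlice[a] += cntSlice[b];
    cntInter[a] += cntInter[b];
  }
};

// Jaccard index between the seed's connected component of
// {values > t} (cross-section in `indexSlice`, 1-based) and the hand ROI,
// for every threshold t, in one sweep: voxels are activated in descending
// intensity order and merged by union-find, tracking per-component counts
// of index-slice voxels and of ROI overlap. `thresholds` must be sorted
// descending; returns the Jaccard values in the same order.
// [[Rcpp::export(name = ".jaccard_scan")]]
NumericVector jaccard_scan(NumericVector values, IntegerVector dim, int seed,
                           NumericVector thresholds, LogicalVector roiSlice,
                           int indexSlice, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  if (values.size() != n) stop("values length does not match dim");
  if (roiSlice.size() != nx * ny) stop("roiSlice length does not match slice");
  if (seed < 1 || seed > n) stop("seed out of bounds");
  for (R_xlen_t i = 1; i < thresholds.size(); ++i)
    if (thresholds[i] > thresholds[i - 1])
      stop("thresholds must be sorted descending");

  std::vector<int> dxs, dys, dzs;
  neighborOffsets(connectivity, dxs, dys, dzs);

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    return values[a] > values[b];
  });

  int nROI = 0;
  for (int i = 0; i < nx * ny; ++i) if (roiSlice[i]) ++nROI;
  const int z0 = indexSlice - 1;

  DSU dsu;
  dsu.parent.assign(n, -1);
  dsu.size.assign(n, 0);
  dsu.cntSlice.assign(n, 0);
  dsu.cntInter.assign(n, 0);
  std::vector<char> active(n, 0);

  const int s = seed - 1;
  NumericVector out(thresholds.size());
  int ptr = 0;
  for (R_xlen_t ti = 0; ti < thresholds.size(); ++ti) {
    const double t = thresholds[ti];
    while (ptr < n && values[order[ptr]] > t) {
      int v = order[ptr++];
      dsu.parent[v] = v;
      dsu.size[v] = 1;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      int inSlice = (z == z0) ? 1 : 0;
      dsu.cntSlice[v] = inSlice;
      dsu.cntInter[v] = (inSlice && roiSlice[x + nx * y]) ? 1 : 0;
      active[v] = 1;
      for (size_t k = 0; k < dxs.size(); ++k) {
        int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (active[w]) dsu.unite(v, w);
      }
    }
    if (!active[s]) {
      out[ti] = 0.0;
    } else {
      int r = dsu.find(s);
      int inter = dsu.cntInter[r];
      int uni = nROI + dsu.cntSlice[r] - inter;
      out[ti] = (uni == 0) ? 0.0 : (double)inter / uni;
    }
  }
  return out;
}
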
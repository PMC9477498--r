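#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Threshold-free cluster enhancement on a 3D grid, face (6-)connectivity.
// For each height h = dh, 2dh, ... <= max(map), every suprathreshold voxel
// accrues extent(cluster at h)^E * h^H * dh. Only strictly positive support
// is enhanced (one-sided statistic maps); a non-positive map returns zeros.
// Clusters are rebuilt per height over the suprathreshold prefix of the
// value-sorted voxel list, so cost is O(n_heights * |suprathreshold|).
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector map, IntegerVector dims,
                       double E, double H, double dh) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  if (map.size() != V) stop("map length does not match grid dims");
  if (dh <= 0) stop("dh must be positive");

  NumericVector out(V, 0.0);
  double mx = 0.0;
  for (int i = 0; i < V; ++i) if (map[i] > mx) mx = map[i];
  if (mx <= 0.0) return out;

  // Voxels sorted by value descending: the suprathreshold set at any height
  // is a prefix of this order.
  std::vector<int> order;
  order.reserve(V);
  for (int i = 0; i < V; ++i) if (map[i] > 0.0) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return map[a] > map[b]; });
  const int P = (int)order.size();

  std::vector<int> parent(V), sz(V);
  std::vector<char> active(V, 0);
  const int sx = 1, sy = nx, sz3 = nx * ny;

  const int n_steps = (int)std::floor(mx / dh);
  for (int s = 1; s <= n_steps; ++s) {
    const double h = s * dh;
    // prefix length at this height
    int m = 0;
    while (m < P && map[order[m]] >= h) ++m;
    if (m == 0) break;
    // build clusters over the prefix
    for (int k = 0; k < m; ++k) {
      int v = order[k];
      parent[v] = v; sz[v] = 1; active[v] = 1;
    }
    for (int k = 0; k < m; ++k) {
      int v = order[k];
      int x = v % nx, y = (v / nx) % ny, z = v / sz3;
      int nb;
      // face neighbours; union when both active
      if (x + 1 < nx && active[nb = v + sx]) {
        int ra = uf_find(parent, v), rb = uf_find(parent, nb);
        if (ra != rb) { parent[rb] = ra; sz[ra] += sz[rb]; }
      }
      if (y + 1 < ny && active[nb = v + sy]) {
        int ra = uf_find(parent, v), rb = uf_find(parent, nb);
        if (ra != rb) { parent[rb] = ra; sz[ra] += sz[rb]; }
      }
      if (z + 1 < nz && active[nb = v + sz3]) {
        int ra = uf_find(parent, v), rb = uf_find(parent, nb);
        if (ra != rb) { parent[rb] = ra; sz[ra] += sz[rb]; }
      }
    }
    const double hterm = std::pow(h, H) * dh;
    for (int k = 0; k < m; ++k) {
      int v = order[k];
      out[v] += std::pow((double)sz[uf_find(parent, v)], E) * hterm;
    }
    // deactivate for the next height's rebuild
    for (int k = 0; k < m; ++k) active[order[k]] = 0;
  }
  return out;
}

// Connected-component labels of a binary 3D mask, face connectivity.
// Returns 0 for background, 1..n_clusters for foreground, labelled in
// first-voxel order.
// [[Rcpp::export(name = ".label_clusters_cpp")]]
IntegerVector label_clusters_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int V = nx * ny * nz;
  if (mask.size() != V) stop("mask length does not match grid dims");
  std::vector<int> parent(V), sz(V, 0);
  for (int i = 0; i < V; ++i) parent[i] = i;
  const int sy = nx, sz3 = nx * ny;
  for (int v = 0; v < V; ++v) {
    if (!mask[v]) continue;
    int x = v % nx, y = (v / nx) % ny, z = v / sz3;
    int nb;
    if (x + 1 < nx && mask[nb = v + 1]) {
      int ra = uf_find(parent, v), rb = uf_find(parent, nb);
      if (ra != rb) parent[rb] = ra;
    }
    if (y + 1 < ny && mask[nb = v + sy]) {
      int ra = uf_find(parent, v), rb = uf_find(parent, nb);
      if (ra != rb) parent[rb] = ra;
    }
    if (z + 1 < nz && mask[nb = v + sz3]) {
      int ra = uf_find(parent, v), rb = uf_find(parent, nb);
      if (ra != rb) parent[rb] = ra;
    }
  }
  IntegerVector lab(V, 0);
  std::vector<int> remap(V, 0);
  int next_lab = 0;
  for (int v = 0; v < V; ++v) {
    if (!mask[v]) continue;
    int r = uf_find(parent, v);
    if (remap[r] == 0) remap[r] = ++next_lab;
    lab[v] = remap[r];
  }
  return lab;
}
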
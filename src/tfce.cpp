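#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Neighbor offsets for 6/18/26-connectivity on a 3D grid.
static void neighbor_offsets(int connectivity,
                             std::vector<int> &dx, std::vector<int> &dy,
                             std::vector<int> &dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (manh == 0) continue;
        if ((connectivity == 6 && manh > 1) ||
            (connectivity == 18 && manh > 2)) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// Flood-fill labeling of the active set. active[v] true for foreground.
// Writes labels 1..n_comp into label (0 background) and component sizes
// (indexed by label-1) into comp_size. Returns n_comp.
static int label_active(const std::vector<char> &active,
                        int d1, int d2, int d3,
                        const std::vector<int> &dx, const std::vector<int> &dy,
                        const std::vector<int> &dz,
                        std::vector<int> &label, std::vector<int> &comp_size,
                        std::vector<int> &stack) {
  const int V = d1 * d2 * d3;
  std::fill(label.begin(), label.end(), 0);
  comp_size.clear();
  int n_comp = 0;
  const int nn = (int)dx.size();
  for (int v = 0; v < V; ++v) {
    if (!active[v] || label[v]) continue;
    ++n_comp;
    int sz = 0;
    stack.clear();
    stack.push_back(v);
    label[v] = n_comp;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      ++sz;
      int ui = u % d1, uj = (u / d1) % d2, uk = u / (d1 * d2);
      for (int t = 0; t < nn; ++t) {
        int ni = ui + dx[t], nj = uj + dy[t], nk = uk + dz[t];
        if (ni < 0 || ni >= d1 || nj < 0 || nj >= d2 || nk < 0 || nk >= d3)
          continue;
        int w = ni + d1 * (nj + d2 * nk);
        if (active[w] && !label[w]) {
          label[w] = n_comp;
          stack.push_back(w);
        }
      }
    }
    comp_size.push_back(sz);
  }
  return n_comp;
}

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int V = d1 * d2 * d3;
  if (mask.size() != V) stop("mask length does not match dims");
  std::vector<int> dx, dy, dz;
  neighbor_offsets(connectivity, dx, dy, dz);
  std::vector<char> active(V);
  for (int v = 0; v < V; ++v) active[v] = (mask[v] == TRUE);
  std::vector<int> label(V), comp_size, stack;
  int n_comp = label_active(active, d1, d2, d3, dx, dy, dz,
                            label, comp_size, stack);
  IntegerVector out(V);
  for (int v = 0; v < V; ++v) out[v] = label[v];
  out.attr("n_components") = n_comp;
  return out;
}

// Threshold-free cluster enhancement of a non-negative map. For each voxel p
// the enhanced value is sum over thresholds h = dh, 2dh, ... <= max of
// e(h)^E * h^H * dh, with e(h) the voxel count of the connected component
// containing p in the supra-threshold set {v : x[v] >= h}. Voxels outside
// the mask, and non-positive voxels, get 0.
// If n_steps > 0, thresholds are h = xmax * k / n_steps for k = 1..n_steps
// (exactly n_steps of them, no floating-point boundary ambiguity at the map
// maximum); otherwise h = dh * k while h <= xmax.
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector x, IntegerVector dims, LogicalVector mask,
                       double E, double H, double dh, int n_steps,
                       int connectivity) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int V = d1 * d2 * d3;
  if (x.size() != V || mask.size() != V) stop("map/mask length mismatch");
  NumericVector out(V); // zero-initialized

  double xmax = 0.0;
  std::vector<double> val(V, 0.0);
  for (int v = 0; v < V; ++v) {
    if (mask[v] == TRUE) {
      double xv = x[v];
      if (ISNAN(xv)) stop("non-finite value inside mask");
      if (xv > 0) {
        val[v] = xv;
        if (xv > xmax) xmax = xv;
      }
    }
  }
  if (xmax <= 0.0) return out;
  if (n_steps <= 0 && dh <= 0.0) stop("dh must be positive");
  if (n_steps > 0) dh = xmax / n_steps;

  std::vector<int> dx, dy, dz;
  neighbor_offsets(connectivity, dx, dy, dz);
  std::vector<char> active(V);
  std::vector<int> label(V), comp_size, stack;

  // thresholds as k * dh (not accumulated) so the step count is exactly
  // reproducible across implementations
  for (int k = 1; ; ++k) {
    if (n_steps > 0 && k > n_steps) break;
    // the top threshold is pinned to xmax itself: (xmax * k) / n_steps can
    // round one ulp above xmax and silently drop the final step
    double h = (n_steps > 0)
      ? (k == n_steps ? xmax : xmax * k / n_steps)
      : dh * k;
    if (n_steps <= 0 && h > xmax) break;
    for (int v = 0; v < V; ++v) active[v] = (val[v] >= h);
    int n_comp = label_active(active, d1, d2, d3, dx, dy, dz,
                              label, comp_size, stack);
    if (n_comp == 0) break;
    std::vector<double> incr(n_comp);
    const double hH = std::pow(h, H);
    for (int c = 0; c < n_comp; ++c)
      incr[c] = std::pow((double)comp_size[c], E) * hH * dh;
    for (int v = 0; v < V; ++v)
      if (label[v]) out[v] += incr[label[v] - 1];
  }
  return out;
}
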
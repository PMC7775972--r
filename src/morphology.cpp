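#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 6-connected component labelling of a 3D logical volume.
// Returns an integer volume: 0 for background, 1..K component labels,
// with labels ordered by discovery (use tabulate() to find the largest).
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}

struct QVox {
  double q;
  R_xlen_t idx;
};
struct QVoxLess {
  bool operator()(const QVox &a, const QVox &b) const { return a.q < b.q; }
};

// Quality-guided region-growing phase unwrapping on a 3D grid.
// Each connected region of the mask is grown independently from its
// highest-quality voxel (which keeps its wrapped value, so the inter-region
// 2*pi*k offset is unconstrained). When a voxel is admitted, its phase is
// unwrapped against the already-unwrapped neighbour it was queued from.
// [[Rcpp::export(name = ".unwrap_rg")]]
NumericVector unwrap_rg(NumericVector wrapped, LogicalVector mask,
                        NumericVector quality, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out = clone(wrapped);
  std::vector<char> done(n, 0);
  const double TWO_PI = 2.0 * M_PI;

  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};

  // Seeds: process voxels in decreasing quality; a voxel that is still
  // unvisited when reached starts a new region.
  std::vector<R_xlen_t> order;
  order.reserve(n);
  for (R_xlen_t s = 0; s < n; ++s)
    if (mask[s]) order.push_back(s);
  std::sort(order.begin(), order.end(), [&](R_xlen_t a, R_xlen_t b) {
    return quality[a] > quality[b];
  });

  std::priority_queue<QVox, std::vector<QVox>, QVoxLess> pq;
  for (R_xlen_t oi = 0; oi < (R_xlen_t)order.size(); ++oi) {
    R_xlen_t seed = order[oi];
    if (done[seed]) continue;
    done[seed] = 1;
    out[seed] = wrapped[seed];
    pq.push({quality[seed], seed});
    while (!pq.empty()) {
      QVox top = pq.top();
      pq.pop();
      R_xlen_t v = top.idx;
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (!mask[w] || done[w]) continue;
        double diff = wrapped[w] - out[v];
        diff -= TWO_PI * std::round(diff / TWO_PI);
        out[w] = out[v] + diff;
        done[w] = 1;
        pq.push({quality[w], w});
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
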
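#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Neighbour offsets for 4- and 8-connectivity, row-major (dr, dc) pairs.
static const int DR4[] = {-1, 1, 0, 0};
static const int DC4[] = {0, 0, -1, 1};
static const int DR8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC8[] = {0, 0, -1, 1, -1, 1, -1, 1};

// Connected-component labeling of a logical mask. Labels are assigned
// 1..N in raster order (row-major) of each component's first pixel, so
// the labeling is deterministic and canonical by construction.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  const int nn = (connectivity == 4) ? 4 : 8;
  const int *dr = (connectivity == 4) ? DR4 : DR8;
  const int *dc = (connectivity == 4) ? DC4 : DC8;
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  // raster order: scan rows top to bottom, columns left to right
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r * W + c);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p / W, pc = p % W;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
          if (!mask(qr, qc) || lab(qr, qc) != 0) continue;
          lab(qr, qc) = next;
          stack.push_back(qr * W + qc);
        }
      }
    }
  }
  return lab;
}

struct WsNode {
  double value;   // (smoothed) distance-map value, flood high to low
  long long order; // insertion counter: FIFO tie-break for determinism
  int idx;        // linear index, row-major
};

struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.value != b.value) return a.value < b.value; // max-heap on value
    return a.order > b.order;                         // earlier first
  }
};

// Marker-based watershed on a distance map, restricted to the pore mask.
// Pixels are claimed in order of decreasing distance-map value starting
// from the marker pixels; each unlabeled masked neighbour inherits the
// label of the basin that reaches it first. Deterministic: ties in value
// are resolved by insertion order.
// [[Rcpp::export(name = ".ws_flood")]]
IntegerMatrix ws_flood(NumericMatrix dist, IntegerMatrix markers,
                       LogicalMatrix mask, int connectivity) {
  const int H = dist.nrow(), W = dist.ncol();
  if (markers.nrow() != H || markers.ncol() != W ||
      mask.nrow() != H || mask.ncol() != W)
    stop("dist, markers and mask must have identical dimensions");
  const int nn = (connectivity == 4) ? 4 : 8;
  const int *dr = (connectivity == 4) ? DR4 : DR8;
  const int *dc = (connectivity == 4) ? DC4 : DC8;

  IntegerMatrix lab(H, W);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long counter = 0;

  // seed with marker pixels, raster order
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      if (markers(r, c) > 0 && mask(r, c)) {
        lab(r, c) = markers(r, c);
        pq.push(WsNode{dist(r, c), counter++, r * W + c});
      }

  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    int pr = nd.idx / W, pc = nd.idx % W;
    int l = lab(pr, pc);
    for (int k = 0; k < nn; ++k) {
      int qr = pr + dr[k], qc = pc + dc[k];
      if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
      if (!mask(qr, qc) || lab(qr, qc) != 0) continue;
      lab(qr, qc) = l;
      pq.push(WsNode{dist(qr, qc), counter++, qr * W + qc});
    }
  }
  return lab;
}
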
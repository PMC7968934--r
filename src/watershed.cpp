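#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Marker-controlled watershed by priority flooding (Meyer's algorithm).
// elevation: surface to flood (lower = flooded first); markers: initial
// labels (>0) at seed pixels; mask: flooding is restricted to true pixels.
// 8-connectivity.  Every reachable mask pixel receives the label of the
// marker whose basin floods it first; ties resolve by elevation then FIFO
// insertion order, so the result is deterministic.

struct Px {
  double elev;
  long order;
  int idx;
};
struct PxCmp {
  bool operator()(const Px& a, const Px& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;  // min-heap on elevation
    return a.order > b.order;                      // then FIFO
  }
};

// [[Rcpp::export(name = ".ws_flood")]]
IntegerMatrix ws_flood(NumericMatrix elevation, IntegerMatrix markers,
                       LogicalMatrix mask) {
  const int h = elevation.nrow(), w = elevation.ncol();
  if (markers.nrow() != h || markers.ncol() != w ||
      mask.nrow() != h || mask.ncol() != w)
    stop("elevation, markers and mask must share dimensions");

  IntegerMatrix labels(h, w);
  std::priority_queue<Px, std::vector<Px>, PxCmp> pq;
  long order = 0;

  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i)
      if (markers(i, j) > 0 && mask(i, j)) {
        labels(i, j) = markers(i, j);
        pq.push({elevation(i, j), order++, j * h + i});
      }

  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};

  while (!pq.empty()) {
    Px p = pq.top(); pq.pop();
    int i = p.idx % h, j = p.idx / h;
    int lab = labels(i, j);
    for (int k = 0; k < 8; ++k) {
      int ni = i + di[k], nj = j + dj[k];
      if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
      if (!mask(ni, nj) || labels(ni, nj) != 0) continue;
      labels(ni, nj) = lab;
      pq.push({elevation(ni, nj), order++, nj * h + ni});
    }
  }
  return labels;
}
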
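#include <Rcpp.h>
#include <queue>
#include <vector>
#include <tuple>

using namespace Rcpp;

// 8-neighbourhood offsets, fixed order (row-major scan of the 3x3 ring)
static const int DR[8] = {-1, -1, -1,  0, 0,  1, 1, 1};
static const int DC[8] = {-1,  0,  1, -1, 1, -1, 0, 1};

// Connected-component labelling of a binary mask, 8-connectivity.
// Labels are assigned in raster-scan order of each component's first pixel,
// so output is fully deterministic.
// [[Rcpp::export(name = ".cc_label8")]]
IntegerMatrix cc_label8(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int k = 0; k < 8; ++k) {
          int rr = p.first + DR[k], cc = p.second + DC[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// Morphological dilation by a Euclidean disc: a pixel is foreground iff some
// mask pixel lies within `radius` (squared-distance comparison, exact).
// [[Rcpp::export(name = ".dilate_disc")]]
LogicalMatrix dilate_disc(const LogicalMatrix& mask, double radius) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  if (radius < 0) stop("radius must be non-negative");
  const int ri = (int)std::floor(radius);
  const double r2 = radius * radius;
  // precompute disc offsets
  std::vector<int> odr, odc;
  for (int dr = -ri; dr <= ri; ++dr)
    for (int dc = -ri; dc <= ri; ++dc)
      if ((double)(dr * dr + dc * dc) <= r2) {
        odr.push_back(dr);
        odc.push_back(dc);
      }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      for (size_t k = 0; k < odr.size(); ++k) {
        int rr = r + odr[k], cc = c + odc[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc) out(rr, cc) = true;
      }
    }
  return out;
}

struct WsNode {
  double dist;
  long order;   // insertion counter; lower = earlier, wins ties
  int r, c, label;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.dist != b.dist) return a.dist < b.dist; // max-heap on distance
    return a.order > b.order;                     // FIFO among equal heights
  }
};

// Seeded watershed by priority flooding of the distance map: pixels are
// claimed in order of decreasing distance-map height starting from the seed
// pixels, so basins grow downhill from each seed. Ties are broken by
// insertion order, making the output deterministic.
// [[Rcpp::export(name = ".watershed_flood")]]
IntegerMatrix watershed_flood(const NumericMatrix& dist,
                              const LogicalMatrix& region,
                              const IntegerMatrix& seeds) {
  const int nr = dist.nrow(), nc = dist.ncol();
  if (region.nrow() != nr || region.ncol() != nc ||
      seeds.nrow() != nr || seeds.ncol() != nc)
    stop("dist, region and seeds must share dimensions");
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long counter = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0 && region(r, c)) {
        lab(r, c) = seeds(r, c);
        WsNode n = {dist(r, c), counter++, r, c, seeds(r, c)};
        pq.push(n);
      }
  while (!pq.empty()) {
    WsNode n = pq.top();
    pq.pop();
    for (int k = 0; k < 8; ++k) {
      int rr = n.r + DR[k], cc = n.c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!region(rr, cc) || lab(rr, cc) != 0) continue;
      lab(rr, cc) = n.label;
      WsNode m = {dist(rr, cc), counter++, rr, cc, n.label};
      pq.push(m);
    }
  }
  return lab;
}
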
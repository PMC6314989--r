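#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  double v;
  int lin;   // 0-based column-major linear index
};

// max-heap on value; ties broken by smallest linear index, which in
// column-major storage (i fastest) is exactly lexicographic (k, j, i) order
struct Lower {
  bool operator()(const Node &a, const Node &b) const {
    if (a.v != b.v) return a.v < b.v;
    return a.lin > b.lin;
  }
};

} // namespace

// Greedy best-first connected growth of a fixed-size high-intensity region.
// Starts at the seed; at each step adds the highest-valued voxel of the
// search region adjacent (given neighbourhood offsets) to the current
// region. Returns the 1-based linear indices in growth order; fewer than
// nVoxels entries mean the seed's connected component was exhausted.
// [[Rcpp::export]]
IntegerVector growGreedyC(NumericVector values, IntegerVector dims,
                          LogicalVector search, int seedLin, int nVoxels,
                          IntegerMatrix offsets) {
  const int ni = dims[0], nj = dims[1], nk = dims[2];
  const R_xlen_t total = (R_xlen_t)ni * nj * nk;
  if (values.size() != total || search.size() != total)
    stop("growGreedyC: dims do not match array length");
  if (seedLin < 0 || seedLin >= total || !search[seedLin])
    stop("growGreedyC: seed outside the search region");
  if (nVoxels < 1) stop("growGreedyC: nVoxels must be >= 1");

  std::vector<char> inRegion(total, 0);
  std::priority_queue<Node, std::vector<Node>, Lower> frontier;
  std::vector<int> out;
  out.reserve(nVoxels);

  const int nOff = offsets.nrow();
  auto pushNeighbours = [&](int lin) {
    int i = lin % ni, j = (lin / ni) % nj, k = lin / (ni * nj);
    for (int o = 0; o < nOff; ++o) {
      int ii = i + offsets(o, 0), jj = j + offsets(o, 1), kk = k + offsets(o, 2);
      if (ii < 0 || ii >= ni || jj < 0 || jj >= nj || kk < 0 || kk >= nk)
        continue;
      int nb = ii + ni * (jj + (R_xlen_t)nj * kk);
      if (search[nb] && !inRegion[nb])
        frontier.push(Node{values[nb], nb});
    }
  };

  inRegion[seedLin] = 1;
  out.push_back(seedLin + 1);
  pushNeighbours(seedLin);

  while ((int)out.size() < nVoxels && !frontier.empty()) {
    Node best = frontier.top();
    frontier.pop();
    if (inRegion[best.lin]) continue;  // stale duplicate
    inRegion[best.lin] = 1;
    out.push_back(best.lin + 1);
    pushNeighbours(best.lin);
  }
  return wrap(out);
}
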
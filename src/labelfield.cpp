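#include <Rcpp.h>
#include <queue>
#include <vector>
#include <tuple>
#include <cmath>
using namespace Rcpp;

// Capacity-constrained multi-source region growing on a raster.
// Patch seeds grow outward in order of distance from their seed cell; a
// category stops claiming cells once it reaches its target cell count, so
// realized areas track the requested covers while patches stay contiguous.
// A fill pass assigns any cells walled off by exhausted categories, and a
// boundary-swap rebalance pass trims the resulting overshoot.

namespace {
struct QItem {
  double key;
  long order;
  int cell;
  int patch;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.key != b.key) return a.key > b.key;
    return a.order > b.order;  // deterministic tie-break: insertion order
  }
};
}

// seeds: 0-based cell index of each patch seed; patch_cat: 1-based category
// target: cells per category (sums to nr*nc)
// [[Rcpp::export]]
IntegerVector grow_label_field_cpp(int nr, int nc,
                                   IntegerVector seed_row, IntegerVector seed_col,
                                   IntegerVector patch_cat, IntegerVector target) {
  const int ncell = nr * nc;
  const int ncat = target.size();
  std::vector<int> lab(ncell, 0);
  std::vector<int> count(ncat + 1, 0);
  std::vector<double> sx(seed_row.size()), sy(seed_row.size());

  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long order = 0;

  auto push_cell = [&](int r, int c, int patch) {
    double dr = r - sx[patch], dc = c - sy[patch];
    pq.push(QItem{std::sqrt(dr * dr + dc * dc), order++, r * nc + c, patch});
  };

  for (int p = 0; p < seed_row.size(); ++p) {
    sx[p] = seed_row[p];
    sy[p] = seed_col[p];
    push_cell(seed_row[p], seed_col[p], p);
  }

  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};

  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    int cell = it.cell;
    if (lab[cell] != 0) continue;
    int cat = patch_cat[it.patch];
    if (count[cat] >= target[cat - 1]) continue;  // category exhausted
    lab[cell] = cat;
    ++count[cat];
    int r = cell / nc, c = cell % nc;
    for (int d = 0; d < 4; ++d) {
      int rr = r + dr4[d], cc = c + dc4[d];
      if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && lab[rr * nc + cc] == 0)
        push_cell(rr, cc, it.patch);
    }
  }

  // fill pass: cells enclosed by exhausted categories take the nearest
  // assigned neighbour's label (BFS from all assigned cells)
  std::queue<int> bfs;
  for (int cell = 0; cell < ncell; ++cell)
    if (lab[cell] != 0) bfs.push(cell);
  while (!bfs.empty()) {
    int cell = bfs.front(); bfs.pop();
    int r = cell / nc, c = cell % nc;
    for (int d = 0; d < 4; ++d) {
      int rr = r + dr4[d], cc = c + dc4[d];
      if (rr >= 0 && rr < nr && cc >= 0 && cc < nc) {
        int nb = rr * nc + cc;
        if (lab[nb] == 0) {
          lab[nb] = lab[cell];
          ++count[lab[nb]];
          bfs.push(nb);
        }
      }
    }
  }

  // rebalance: flip boundary cells from over- to under-target categories
  for (int pass = 0; pass < 50; ++pass) {
    bool moved = false;
    for (int cell = 0; cell < ncell; ++cell) {
      int cat = lab[cell];
      if (count[cat] <= target[cat - 1]) continue;
      int r = cell / nc, c = cell % nc;
      for (int d = 0; d < 4; ++d) {
        int rr = r + dr4[d], cc = c + dc4[d];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int ncat2 = lab[rr * nc + cc];
        if (ncat2 != cat && count[ncat2] < target[ncat2 - 1]) {
          lab[cell] = ncat2;
          --count[cat];
          ++count[ncat2];
          moved = true;
          break;
        }
      }
    }
    if (!moved) break;
  }

  return IntegerVector(lab.begin(), lab.end());
}
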
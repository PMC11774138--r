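#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Voronoi cells clipped to a rectangle, by incremental half-plane clipping.
// For each site the cell starts as the plot rectangle and is cut by the
// perpendicular bisector of every other site, visited in order of distance;
// once half the distance to the next candidate exceeds the farthest cell
// vertex the remaining candidates cannot cut the cell and the loop stops.
// Each polygon edge carries the index of the site whose bisector created it
// (0 for a plot boundary), which yields the adjacency list and shared
// boundary lengths directly.

namespace {

struct TaggedPoly {
  std::vector<double> x, y;
  std::vector<int> tag;  // tag[k] labels edge (k, k+1 mod n); 0 = boundary
};

// clip convex polygon by half-plane a*x + b*y <= c; new edge tagged newtag
void clip_halfplane(TaggedPoly& p, double a, double b, double c, int newtag) {
  const size_t n = p.x.size();
  if (n == 0) return;
  std::vector<double> s(n);
  for (size_t k = 0; k < n; ++k) s[k] = a * p.x[k] + b * p.y[k] - c;

  TaggedPoly out;
  out.x.reserve(n + 2); out.y.reserve(n + 2); out.tag.reserve(n + 2);
  for (size_t k = 0; k < n; ++k) {
    size_t nx = (k + 1) % n;
    bool in_k = s[k] <= 0.0, in_nx = s[nx] <= 0.0;
    if (in_k) {
      out.x.push_back(p.x[k]); out.y.push_back(p.y[k]);
      if (in_nx) {
        out.tag.push_back(p.tag[k]);
      } else {
        out.tag.push_back(p.tag[k]);
        double t = s[k] / (s[k] - s[nx]);
        out.x.push_back(p.x[k] + t * (p.x[nx] - p.x[k]));
        out.y.push_back(p.y[k] + t * (p.y[nx] - p.y[k]));
        out.tag.push_back(newtag);  // edge running along the bisector
      }
    } else if (in_nx) {
      double t = s[k] / (s[k] - s[nx]);
      out.x.push_back(p.x[k] + t * (p.x[nx] - p.x[k]));
      out.y.push_back(p.y[k] + t * (p.y[nx] - p.y[k]));
      out.tag.push_back(p.tag[k]);  // surviving part of the original edge
    }
  }
  p = std::move(out);
}

double poly_area(const TaggedPoly& p) {
  double a = 0.0;
  size_t n = p.x.size();
  for (size_t k = 0; k < n; ++k) {
    size_t nx = (k + 1) % n;
    a += p.x[k] * p.y[nx] - p.x[nx] * p.y[k];
  }
  return 0.5 * std::fabs(a);
}

}  // namespace

// [[Rcpp::export]]
List voronoi_cells_cpp(NumericVector x, NumericVector y,
                       double xmin, double xmax, double ymin, double ymax) {
  const int n = x.size();
  std::vector<int> ord(n);

  List polys(n);
  NumericVector areas(n);
  std::vector<int> ei, ej;
  std::vector<double> elen;

  for (int i = 0; i < n; ++i) {
    TaggedPoly cell;
    cell.x = {xmin, xmax, xmax, xmin};
    cell.y = {ymin, ymin, ymax, ymax};
    cell.tag = {0, 0, 0, 0};

    // candidates by distance to site i; only the nearest few ever cut the
    // cell, so partially sort the nearest K and fall back to a full sort
    // in the rare case the security radius is not reached within them
    std::vector<std::pair<double, int>> cand;
    cand.reserve(n - 1);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[j] - x[i], dy = y[j] - y[i];
      cand.emplace_back(dx * dx + dy * dy, j);
    }
    size_t K = std::min(cand.size(), static_cast<size_t>(48));
    std::partial_sort(cand.begin(), cand.begin() + K, cand.end());
    bool sorted_all = (K == cand.size());

    for (size_t ci = 0; ci < cand.size(); ++ci) {
      if (ci == K && !sorted_all) {
        std::sort(cand.begin() + K, cand.end());
        sorted_all = true;
      }
      const auto& cj = cand[ci];
      // security radius: farthest cell vertex from the site
      double maxr2 = 0.0;
      for (size_t k = 0; k < cell.x.size(); ++k) {
        double dx = cell.x[k] - x[i], dy = cell.y[k] - y[i];
        double r2 = dx * dx + dy * dy;
        if (r2 > maxr2) maxr2 = r2;
      }
      if (cj.first > 4.0 * maxr2) break;  // dist/2 > max vertex radius
      int j = cj.second;
      // half-plane closer to i than j: (p - m) . (pj - pi) <= 0
      double a = x[j] - x[i], b = y[j] - y[i];
      double c = 0.5 * (a * (x[i] + x[j]) + b * (y[i] + y[j]));
      clip_halfplane(cell, a, b, c, j + 1);
      if (cell.x.empty()) break;  // degenerate (duplicate sites)
    }

    size_t m = cell.x.size();
    NumericMatrix pm(m, 2);
    for (size_t k = 0; k < m; ++k) { pm(k, 0) = cell.x[k]; pm(k, 1) = cell.y[k]; }
    polys[i] = pm;
    areas[i] = poly_area(cell);

    for (size_t k = 0; k < m; ++k) {
      if (cell.tag[k] > 0) {
        size_t nx = (k + 1) % m;
        double dx = cell.x[nx] - cell.x[k], dy = cell.y[nx] - cell.y[k];
        double len = std::sqrt(dx * dx + dy * dy);
        if (len > 0.0) {
          ei.push_back(i + 1);
          ej.push_back(cell.tag[k]);
          elen.push_back(len);
        }
      }
    }
  }

  return List::create(_["polygons"] = polys,
                      _["area"] = areas,
                      _["edge_i"] = wrap(ei),
                      _["edge_j"] = wrap(ej),
                      _["edge_len"] = wrap(elen));
}
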
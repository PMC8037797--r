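#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// GF(2) boundary-matrix reduction of the triangle columns of a Rips
// filtration restricted to dimension <= 2. Columns live over the edge
// ranks (filtration order); the standard left-to-right reduction pairs
// each settled column's lowest one (a cycle-creating edge) with the
// triangle, yielding the dimension-1 persistence pairs.
//
// tri_edges: nt x 3 integer matrix of 1-based edge ranks, rows in
//            filtration order of the triangles.
// n_edges:   number of edges in the filtration.
//
// Returns a list with `edge` and `triangle`, parallel 1-based vectors of
// the persistence pairs.
// [[Rcpp::export]]
List reduce_triangle_columns(IntegerMatrix tri_edges, int n_edges) {
  const int nt = tri_edges.nrow();
  std::vector<int> low_owner(n_edges + 1, 0);
  std::vector< std::vector<int> > stored(nt + 1);
  std::vector<int> pair_edge, pair_tri;
  std::vector<int> col, tmp;
  col.reserve(64);
  tmp.reserve(64);

  for (int t = 1; t <= nt; ++t) {
    col.clear();
    col.push_back(tri_edges(t - 1, 0));
    col.push_back(tri_edges(t - 1, 1));
    col.push_back(tri_edges(t - 1, 2));
    std::sort(col.begin(), col.end());
    while (!col.empty()) {
      const int low = col.back();
      const int owner = low_owner[low];
      if (owner == 0) break;
      const std::vector<int>& other = stored[owner];
      tmp.clear();
      std::set_symmetric_difference(col.begin(), col.end(),
                                    other.begin(), other.end(),
                                    std::back_inserter(tmp));
      col.swap(tmp);
    }
    if (!col.empty()) {
      low_owner[col.back()] = t;
      stored[t] = col;
      pair_edge.push_back(col.back());
      pair_tri.push_back(t);
    }
  }
  return List::create(_["edge"] = wrap(pair_edge),
                      _["triangle"] = wrap(pair_tri));
}
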
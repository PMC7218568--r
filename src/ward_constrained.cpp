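#include <Rcpp.h>
#include <map>
#include <set>
#include <vector>
using namespace Rcpp;

// Connectivity-constrained agglomerative clustering with the Ward objective.
//
// Greedily merges the pair of graph-connected clusters whose fusion causes
// the smallest increase in total within-cluster sum of squares,
//   delta(A, B) = n_A * n_B / (n_A + n_B) * ||c_A - c_B||^2 ,
// the centroid form of the Ward criterion.  Only pairs joined by at least
// one edge of the supplied graph may merge; merged clusters inherit the
// union of their members' neighborhoods.  Ties are broken by the smallest
// (i, j) cluster-index pair so the result is deterministic.
//
// coords: n x d observation coordinates.
// edges:  m x 2 matrix of 0-based endpoint indices (undirected, no self
//         loops required; duplicates are ignored).
// n_clusters: merging stops when this many clusters remain, or earlier if
//         the graph runs out of mergeable (connected) pairs.
//
// Returns 1-based cluster labels, relabeled densely in order of first
// appearance, with attribute "n_groups".
// [[Rcpp::export(name = ".ward_constrained_cpp")]]
IntegerVector ward_constrained_cpp(NumericMatrix coords, IntegerMatrix edges,
                                   int n_clusters) {
  const int n = coords.nrow();
  const int d = coords.ncol();
  if (n_clusters < 1 || n_clusters > n)
    stop("n_clusters must lie in [1, n]");

  std::vector<double> cent(coords.begin(), coords.end()); // column-major n x d
  std::vector<double> csize(n, 1.0);
  std::vector<bool> active(n, true);
  std::vector<int> root(n);
  for (int i = 0; i < n; ++i) root[i] = i;
  // member lists so final labels can be assigned without union-find
  std::vector< std::vector<int> > members(n);
  for (int i = 0; i < n; ++i) members[i].push_back(i);

  auto dist2 = [&](int a, int b) {
    double s = 0.0;
    for (int k = 0; k < d; ++k) {
      double diff = cent[a + (size_t)k * n] - cent[b + (size_t)k * n];
      s += diff * diff;
    }
    return s;
  };
  auto ward_delta = [&](int a, int b) {
    return csize[a] * csize[b] / (csize[a] + csize[b]) * dist2(a, b);
  };

  // neighbor -> ward delta, kept symmetric
  std::vector< std::map<int, double> > nb(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = edges(e, 0), j = edges(e, 1);
    if (i == j) continue;
    if (i < 0 || j < 0 || i >= n || j >= n) stop("edge index out of range");
    if (nb[i].count(j)) continue;
    double w = ward_delta(i, j);
    nb[i][j] = w;
    nb[j][i] = w;
  }

  int n_active = n;
  while (n_active > n_clusters) {
    // locate the cheapest mergeable pair
    double best = R_PosInf;
    int bi = -1, bj = -1;
    for (int i = 0; i < n; ++i) {
      if (!active[i]) continue;
      for (std::map<int, double>::const_iterator it = nb[i].begin();
           it != nb[i].end(); ++it) {
        int j = it->first;
        if (j <= i) continue; // each pair once, smallest-index order
        double w = it->second;
        if (w < best || (w == best && (i < bi || (i == bi && j < bj)))) {
          best = w; bi = i; bj = j;
        }
      }
    }
    if (bi < 0) break; // graph exhausted: only disconnected clusters remain

    // merge bj into bi
    double na = csize[bi], nb_ = csize[bj], nt = na + nb_;
    for (int k = 0; k < d; ++k) {
      size_t off = (size_t)k * n;
      cent[bi + off] = (na * cent[bi + off] + nb_ * cent[bj + off]) / nt;
    }
    csize[bi] = nt;
    active[bj] = false;
    members[bi].insert(members[bi].end(), members[bj].begin(), members[bj].end());
    members[bj].clear();

    // fold bj's neighborhood into bi's and refresh deltas
    std::set<int> touched;
    for (std::map<int, double>::const_iterator it = nb[bj].begin();
         it != nb[bj].end(); ++it)
      if (it->first != bi) touched.insert(it->first);
    for (std::map<int, double>::const_iterator it = nb[bi].begin();
         it != nb[bi].end(); ++it)
      if (it->first != bj) touched.insert(it->first);
    nb[bj].clear();
    nb[bi].clear();
    for (std::set<int>::const_iterator it = touched.begin();
         it != touched.end(); ++it) {
      int k = *it;
      nb[k].erase(bi);
      nb[k].erase(bj);
      double w = ward_delta(bi, k);
      nb[bi][k] = w;
      nb[k][bi] = w;
    }
    --n_active;
  }

  IntegerVector labels(n);
  int next_id = 0;
  std::vector<int> id_of(n, -1);
  for (int i = 0; i < n; ++i) {
    if (!active[i]) continue;
    id_of[i] = next_id++;
  }
  // relabel densely by first-appearing member so output is order-stable
  std::vector<int> first_member(next_id, n);
  for (int i = 0; i < n; ++i)
    if (active[i])
      for (size_t m = 0; m < members[i].size(); ++m)
        if (members[i][m] < first_member[id_of[i]])
          first_member[id_of[i]] = members[i][m];
  std::vector<int> order(next_id);
  for (int c = 0; c < next_id; ++c) order[c] = c;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    return first_member[a] < first_member[b];
  });
  std::vector<int> dense(next_id);
  for (int r = 0; r < next_id; ++r) dense[order[r]] = r + 1;
  for (int i = 0; i < n; ++i)
    if (active[i])
      for (size_t m = 0; m < members[i].size(); ++m)
        labels[members[i][m]] = dense[id_of[i]];

  labels.attr("n_groups") = next_id;
  return labels;
}
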
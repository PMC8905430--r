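// Batch screening of edge subsets for the brute-force reference counter.
// Shares no code with the search engine: connectivity is decided by a plain
// union-find over the (undirected skeleton of the) subset's endpoints.

#include <Rcpp.h>

#include <vector>

namespace {

int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

}  // namespace

// subsets: j x N matrix of 1-based edge indices into src/dst/time.
// Returns per column: number of distinct nodes, connectivity of the induced
// graph, and the timestamp span (max - min).
// [[Rcpp::export]]
Rcpp::List cpp_screen_subsets(Rcpp::IntegerVector src, Rcpp::IntegerVector dst,
                              Rcpp::NumericVector time,
                              Rcpp::IntegerMatrix subsets) {
  const int j = subsets.nrow();
  const int ns = subsets.ncol();
  Rcpp::IntegerVector n_nodes(ns);
  Rcpp::LogicalVector connected(ns);
  Rcpp::NumericVector span(ns);

  std::vector<int> ends(2 * j), local(2 * j), parent(2 * j);
  for (int s = 0; s < ns; ++s) {
    int nloc = 0;
    double tmin = R_PosInf, tmax = R_NegInf;
    for (int r = 0; r < j; ++r) {
      int e = subsets(r, s) - 1;
      ends[2 * r] = src[e];
      ends[2 * r + 1] = dst[e];
      double t = time[e];
      if (t < tmin) tmin = t;
      if (t > tmax) tmax = t;
    }
    // dense local relabeling by linear search (at most 2j endpoints)
    for (int i = 0; i < 2 * j; ++i) {
      int id = -1;
      for (int p = 0; p < i; ++p) {
        if (ends[p] == ends[i]) {
          id = local[p];
          break;
        }
      }
      local[i] = (id >= 0) ? id : nloc++;
    }
    for (int i = 0; i < nloc; ++i) parent[i] = i;
    int comps = nloc;
    for (int r = 0; r < j; ++r) {
      int a = uf_find(parent, local[2 * r]);
      int b = uf_find(parent, local[2 * r + 1]);
      if (a != b) {
        parent[a] = b;
        --comps;
      }
    }
    n_nodes[s] = nloc;
    connected[s] = (comps == 1);
    span[s] = tmax - tmin;
  }
  return Rcpp::List::create(Rcpp::Named("n_nodes") = n_nodes,
                            Rcpp::Named("connected") = connected,
                            Rcpp::Named("span") = span);
}
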
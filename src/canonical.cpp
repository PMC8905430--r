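// Canonical labeling of small temporal motifs.
//
// Node ordering is fixed by (1) an invariant refinement -- degree descending,
// then the sorted list of incident (rank, direction) pairs, iterated to a
// stable coloring against neighbor colors -- and (2) an exhaustive
// lexicographic-minimum search over the orderings consistent with the
// refinement. True twin nodes (identical concrete incidence records) are
// interchangeable under an automorphism, so only distinct arrangements of
// twin classes are enumerated. The result is a complete invariant: equal
// strings iff a rank- and direction-preserving node bijection exists.

#include <Rcpp.h>

#include <algorithm>
#include <cstdio>
#include <functional>
#include <map>
#include <string>
#include <vector>

#include "canonical.h"

namespace {

struct Rec {
  int rank;
  int tag;  // 0 = out / undirected, 1 = in
  int nb;   // neighbor node id
  bool operator<(const Rec& o) const {
    if (rank != o.rank) return rank < o.rank;
    if (tag != o.tag) return tag < o.tag;
    return nb < o.nb;
  }
  bool operator==(const Rec& o) const {
    return rank == o.rank && tag == o.tag && nb == o.nb;
  }
};

void append_int(std::string& s, int x) {
  char buf[16];
  int n = std::snprintf(buf, sizeof(buf), "%d", x);
  s.append(buf, n);
}

}  // namespace

std::string canonical_motif(const std::vector<MotifEdge>& edges, int n_nodes,
                            bool directed) {
  const int n = n_nodes;
  std::vector<std::vector<Rec>> recs(n);
  for (const MotifEdge& e : edges) {
    recs[e.u].push_back({e.rank, 0, e.v});
    recs[e.v].push_back({e.rank, directed ? 1 : 0, e.u});
  }
  for (int w = 0; w < n; ++w) std::sort(recs[w].begin(), recs[w].end());

  // Initial coloring: degree descending, then sorted (rank, tag) list.
  std::vector<std::vector<int>> key(n);
  for (int w = 0; w < n; ++w) {
    key[w].push_back(-static_cast<int>(recs[w].size()));
    for (const Rec& r : recs[w]) {
      key[w].push_back(r.rank);
      key[w].push_back(r.tag);
    }
  }
  std::vector<int> color(n);
  {
    std::map<std::vector<int>, int> uniq;
    for (int w = 0; w < n; ++w) uniq[key[w]] = 0;
    int c = 0;
    for (auto& kv : uniq) kv.second = c++;
    for (int w = 0; w < n; ++w) color[w] = uniq[key[w]];
  }

  // Refine against neighbor colors until stable. Cell order stays invariant:
  // cells are ordered by (parent color, refinement subkey).
  int n_colors = 0;
  for (int w = 0; w < n; ++w) n_colors = std::max(n_colors, color[w] + 1);
  for (;;) {
    std::vector<std::vector<int>> sub(n);
    for (int w = 0; w < n; ++w) {
      sub[w].push_back(color[w]);
      std::vector<std::vector<int>> items;
      for (const Rec& r : recs[w])
        items.push_back({r.rank, r.tag, color[r.nb]});
      std::sort(items.begin(), items.end());
      for (const auto& it : items)
        sub[w].insert(sub[w].end(), it.begin(), it.end());
    }
    std::map<std::vector<int>, int> uniq;
    for (int w = 0; w < n; ++w) uniq[sub[w]] = 0;
    int c = 0;
    for (auto& kv : uniq) kv.second = c++;
    if (c == n_colors) break;
    for (int w = 0; w < n; ++w) color[w] = uniq[sub[w]];
    n_colors = c;
  }

  // Cells in color order; twin classes (identical concrete records) within
  // each cell are interchangeable, so permute class labels only.
  std::vector<std::vector<int>> cells(n_colors);
  for (int w = 0; w < n; ++w) cells[color[w]].push_back(w);

  // For each cell: members grouped by identical record vectors.
  // arrangement = a distinct permutation of the multiset of group labels.
  std::vector<std::vector<int>> cell_groups(n_colors);  // group label per member
  std::vector<std::vector<std::vector<int>>> cell_members(n_colors);
  double total_orderings = 1.0;
  for (int c = 0; c < n_colors; ++c) {
    std::map<std::vector<Rec>, int> groups;
    for (int w : cells[c]) {
      auto it = groups.find(recs[w]);
      int g;
      if (it == groups.end()) {
        g = static_cast<int>(groups.size());
        groups.emplace(recs[w], g);
        cell_members[c].push_back({});
      } else {
        g = it->second;
      }
      cell_groups[c].push_back(g);
      cell_members[c][g].push_back(w);
    }
    std::sort(cell_groups[c].begin(), cell_groups[c].end());
    // distinct permutations = multinomial(|cell|; group sizes)
    double perms = 1.0;
    for (size_t i = 2; i <= cell_groups[c].size(); ++i) perms *= i;
    for (const auto& g : cell_members[c])
      for (size_t i = 2; i <= g.size(); ++i) perms /= i;
    total_orderings *= perms;
    if (total_orderings > 1e6)
      Rcpp::stop("motif is too symmetric for exhaustive canonization");
  }

  std::vector<int> order(n), pos(n);
  std::string best;
  bool have_best = false;
  std::string cur;

  // Enumerate orderings: for the current group-label sequences, assign
  // concrete members (twins in fixed relative order), encode, keep minimum.
  std::function<void(int)> walk = [&](int c) {
    if (c == n_colors) {
      int idx = 0;
      std::vector<std::vector<int>> used(n_colors);
      for (int cc = 0; cc < n_colors; ++cc) {
        std::vector<int> taken(cell_members[cc].size(), 0);
        for (int g : cell_groups[cc])
          order[idx++] = cell_members[cc][g][taken[g]++];
      }
      for (int i = 0; i < n; ++i) pos[order[i]] = i;
      cur.clear();
      std::vector<Rec> rr;
      for (int i = 0; i < n; ++i) {
        int w = order[i];
        rr.clear();
        for (const Rec& r : recs[w]) rr.push_back({r.rank, r.tag, pos[r.nb]});
        std::sort(rr.begin(), rr.end(),
                  [](const Rec& a, const Rec& b) {
                    if (a.rank != b.rank) return a.rank < b.rank;
                    if (a.nb != b.nb) return a.nb < b.nb;
                    return a.tag < b.tag;
                  });
        for (const Rec& r : rr) {
          if (!cur.empty()) cur.push_back(';');
          cur.append("(n");
          append_int(cur, i);
          cur.push_back(',');
          append_int(cur, r.rank);
          cur.append(",n");
          append_int(cur, r.nb);
          if (directed) cur.append(r.tag == 0 ? ",o" : ",i");
          cur.push_back(')');
        }
      }
      if (!have_best || cur < best) {
        best = cur;
        have_best = true;
      }
      return;
    }
    // iterate distinct permutations of this cell's group labels
    std::vector<int>& g = cell_groups[c];
    std::sort(g.begin(), g.end());
    do {
      walk(c + 1);
    } while (std::next_permutation(g.begin(), g.end()));
  };
  walk(0);
  return best;
}

// [[Rcpp::export]]
Rcpp::String cpp_canonical_form(Rcpp::IntegerVector u, Rcpp::IntegerVector v,
                                Rcpp::IntegerVector rank, int n_nodes,
                                bool directed) {
  std::vector<MotifEdge> edges(u.size());
  for (int i = 0; i < u.size(); ++i)
    edges[i] = {u[i] - 1, v[i] - 1, rank[i]};
  return canonical_motif(edges, n_nodes, directed);
}

// Standardize + canonize a batch of edge subsets of one target graph.
// src/dst are 1-based dense node ids; each subset is a vector of 1-based
// edge indices.
// [[Rcpp::export]]
Rcpp::CharacterVector cpp_motif_keys(Rcpp::IntegerVector src,
                                     Rcpp::IntegerVector dst,
                                     Rcpp::NumericVector time,
                                     Rcpp::List subsets, bool directed) {
  int ns = subsets.size();
  Rcpp::CharacterVector out(ns);
  std::vector<MotifEdge> edges;
  std::vector<double> ts;
  std::vector<int> local_of;  // node relabeling scratch
  int n_total = 0;
  for (int i = 0; i < src.size(); ++i)
    n_total = std::max(n_total, std::max(src[i], dst[i]));
  local_of.assign(n_total + 1, -1);
  std::vector<int> touched;
  for (int s = 0; s < ns; ++s) {
    Rcpp::IntegerVector ids = subsets[s];
    edges.clear();
    ts.clear();
    touched.clear();
    for (int j = 0; j < ids.size(); ++j) ts.push_back(time[ids[j] - 1]);
    std::vector<double> uniq(ts);
    std::sort(uniq.begin(), uniq.end());
    uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
    int nloc = 0;
    for (int j = 0; j < ids.size(); ++j) {
      int e = ids[j] - 1;
      int a = src[e], b = dst[e];
      if (local_of[a] < 0) { local_of[a] = nloc++; touched.push_back(a); }
      if (local_of[b] < 0) { local_of[b] = nloc++; touched.push_back(b); }
      int r = 1 + static_cast<int>(std::lower_bound(uniq.begin(), uniq.end(),
                                                    ts[j]) - uniq.begin());
      edges.push_back({local_of[a], local_of[b], r});
    }
    out[s] = canonical_motif(edges, nloc, directed);
    for (int a : touched) local_of[a] = -1;
  }
  return out;
}
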
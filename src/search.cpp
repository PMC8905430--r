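// Seed-and-extend enumeration of delta-window connected subgraphs.
//
// Every edge of the target is a seed; a seed carries the minimum timestamp
// of every subgraph grown from it, so extensions only admit timestamps in
// [minTime, minTime + delta] (the admission interval is constant per seed
// because maxTime + lambda = minTime + delta). A global visited set keyed by
// the sorted edge-id tuple guarantees each subgraph is counted exactly once
// even when its minimum timestamp is shared by several seed edges. Each newly
// recorded subgraph is extended by one edge incident to ANY of its nodes:
// extending only from the endpoints of the last added edge would restrict
// growth to adjacent-edge chains and lose, e.g., a four-edge path whose
// earliest edge is interior.

#include <Rcpp.h>

#include <algorithm>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

#include "canonical.h"

namespace {

class Engine {
 public:
  Engine(const std::vector<int>& src, const std::vector<int>& dst,
         const std::vector<double>& time, int n_nodes, bool directed,
         double delta, int k, int l, double cap)
      : src_(src), dst_(dst), time_(time), n_(n_nodes), directed_(directed),
        delta_(delta), k_(k), l_(l), cap_(cap) {
    m_ = static_cast<int>(src_.size());
    inc_.assign(n_, {});
    for (int e = 0; e < m_; ++e) {  // ascending edge id per node
      inc_[src_[e]].push_back(e);
      inc_[dst_[e]].push_back(e);
    }
    in_s_.assign(m_, 0);
    node_cnt_.assign(n_, 0);
    local_of_.assign(n_, -1);
  }

  void run() {
    for (int e = 0; e < m_; ++e) {
      min_time_ = time_[e];
      add_edge(e);
      visited_.insert(key());
      count_current();
      extend();
      remove_edge(e);
    }
  }

  double n_subgraphs() const { return static_cast<double>(visited_.size()); }
  const std::unordered_map<std::string, double>& counts() const {
    return counts_;
  }

 private:
  std::string key() const {
    return std::string(reinterpret_cast<const char*>(s_.data()),
                       s_.size() * sizeof(int));
  }

  void add_edge(int e) {
    s_.insert(std::upper_bound(s_.begin(), s_.end(), e), e);
    in_s_[e] = 1;
    for (int w : {src_[e], dst_[e]}) {
      if (node_cnt_[w]++ == 0) nodes_in_s_.push_back(w);
    }
  }

  void remove_edge(int e) {
    s_.erase(std::lower_bound(s_.begin(), s_.end(), e));
    in_s_[e] = 0;
    --node_cnt_[src_[e]];
    --node_cnt_[dst_[e]];
    while (!nodes_in_s_.empty() && node_cnt_[nodes_in_s_.back()] == 0)
      nodes_in_s_.pop_back();
  }

  void count_current() {
    if (n_subgraphs() > cap_)
      Rcpp::stop("subgraph limit exceeded (max_subgraphs = %.0f)", cap_);
    // standardize timestamps to ranks, relabel nodes densely, canonize
    std::vector<double> uniq;
    uniq.reserve(s_.size());
    for (int e : s_) uniq.push_back(time_[e]);
    std::sort(uniq.begin(), uniq.end());
    uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
    int nloc = 0;
    for (int e : s_) {
      for (int w : {src_[e], dst_[e]}) {
        if (local_of_[w] < 0) local_of_[w] = nloc++;
      }
    }
    std::vector<MotifEdge> edges;
    edges.reserve(s_.size());
    for (int e : s_) {
      int r = 1 + static_cast<int>(std::lower_bound(uniq.begin(), uniq.end(),
                                                    time_[e]) - uniq.begin());
      edges.push_back({local_of_[src_[e]], local_of_[dst_[e]], r});
    }
    counts_[canonical_motif(edges, nloc, directed_)] += 1.0;
    for (int e : s_) {
      local_of_[src_[e]] = -1;
      local_of_[dst_[e]] = -1;
    }
  }

  void extend() {
    if (static_cast<int>(s_.size()) >= l_) return;
    for (size_t wi = 0; wi < nodes_in_s_.size(); ++wi) {
      int w = nodes_in_s_[wi];
      for (int e : inc_[w]) {
        if (in_s_[e]) continue;
        double t = time_[e];
        if (t < min_time_ || t > min_time_ + delta_) continue;
        bool new_node = node_cnt_[src_[e]] == 0 || node_cnt_[dst_[e]] == 0;
        if (new_node && static_cast<int>(nodes_in_s_.size()) >= k_) continue;
        add_edge(e);
        if (visited_.insert(key()).second) {
          count_current();
          extend();
        }
        remove_edge(e);
      }
    }
  }

  const std::vector<int>& src_;
  const std::vector<int>& dst_;
  const std::vector<double>& time_;
  int n_, m_;
  bool directed_;
  double delta_;
  int k_, l_;
  double cap_;

  std::vector<std::vector<int>> inc_;
  std::vector<int> s_;         // sorted edge ids of the current subgraph
  std::vector<char> in_s_;
  std::vector<int> node_cnt_;  // incident edges of the subgraph per node
  std::vector<int> nodes_in_s_;
  std::vector<int> local_of_;
  double min_time_ = 0.0;
  std::unordered_set<std::string> visited_;
  std::unordered_map<std::string, double> counts_;
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_count_motifs(Rcpp::IntegerVector src, Rcpp::IntegerVector dst,
                            Rcpp::NumericVector time, int n_nodes,
                            bool directed, double delta, int k, int l,
                            double max_subgraphs) {
  std::vector<int> s(src.size()), d(dst.size());
  std::vector<double> t(time.size());
  for (int i = 0; i < src.size(); ++i) {
    s[i] = src[i] - 1;
    d[i] = dst[i] - 1;
    t[i] = time[i];
  }
  Engine eng(s, d, t, n_nodes, directed, delta, k, l, max_subgraphs);
  eng.run();
  const auto& cnt = eng.counts();
  Rcpp::CharacterVector canon(cnt.size());
  Rcpp::NumericVector n_occ(cnt.size());
  int i = 0;
  for (const auto& kv : cnt) {
    canon[i] = kv.first;
    n_occ[i] = kv.second;
    ++i;
  }
  return Rcpp::List::create(Rcpp::Named("canonical_form") = canon,
                            Rcpp::Named("count") = n_occ,
                            Rcpp::Named("n_subgraphs") = eng.n_subgraphs());
}
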
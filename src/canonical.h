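#ifndef TEMPORALMOTIFS_CANONICAL_H
#define TEMPORALMOTIFS_CANONICAL_H

#include <string>
#include <vector>

// One motif edge: node ids 0..n-1, rank >= 1.
struct MotifEdge {
  int u;
  int v;
  int rank;
};

// Isomorphism-invariant canonical string for a small temporal motif.
// Grammar: records "(n<i>,<rank>,n<j>)" (undirected) or
// "(n<i>,<rank>,n<j>,o|i)" (directed), joined by ';'. Every edge is emitted
// from both endpoints, node by node in canonical order.
std::string canonical_motif(const std::vector<MotifEdge>& edges, int n_nodes,
                            bool directed);

#endif
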
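---
title: "Counting temporal motifs in a delta window"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting temporal motifs in a delta window}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temporalmotifs)
```

## The model

A temporal graph is a multigraph `G = (V, E)` whose edges are triples
`(source, dest, timestamp)`. Triples are distinct, so parallel edges between
one pair of nodes must differ in timestamp; for an undirected graph the pair
is unordered. Self-loops are excluded: the motif semantics below are defined
on interactions between distinct nodes, and excluding loops at parse time is
the conservative reading.

A **temporal motif** is a connected temporal graph in *standardized* form:
its edge timestamps are ranks with the sorted distinct ranks equal to
`1, 2, …`. Ranks express only the order of events; equal ranks encode
simultaneous events and are allowed as long as the tied edges do not join the
same node pair (same *ordered* pair in the directed case, so `a→b` and `b→a`
may legitimately be simultaneous — they are distinct triples of the target).

Given a window width `delta` and bounds `k` (nodes) and `l` (edges), a motif
**delta-occurs** at every connected subgraph `S` of the target whose
standardization equals the motif and whose timestamp span
`max(t) − min(t)` is at most `delta` (inclusive). The census problem solved
by `count_temporal_motifs()` is: count, for every motif with at most `k`
nodes and at most `l` edges, its number of delta-occurrences. An occurrence
is an edge *subset* — there is no requirement that a node's events be
consecutive, and the chronological-order condition is encoded by
standardization itself, so enumerating subsets is a complete realization of
the matching semantics.

## The search

Every edge of the target is a *seed*. A subgraph is grown from its
minimum-timestamp edge one incident edge at a time, and an extension with
timestamp `t` is admitted iff `minTime ≤ t ≤ minTime + delta`. The textbook
bookkeeping maintains the window as `lambda = delta − maxTime + minTime`
(how much the span may still stretch) with the admission interval
`[minTime, maxTime + lambda]`; since `maxTime + lambda = minTime + delta` is
constant per seed, the engine tests against the constant interval directly.
`update_bounds()`/`window_state()` expose the explicit bookkeeping for
inspection and tests.

Two design points matter for correctness:

* **Global deduplication.** A subgraph whose minimum timestamp is shared by
  two edges is reachable from two seeds, and most subgraphs are reachable
  through many growth orders. A single visited set, keyed by the sorted
  edge-id tuple and kept across all seeds, guarantees exactly-once counting.
  Keys (not subgraphs) are stored; memory still grows linearly with the
  number of distinct subgraphs, which is the dominant cost of an exact
  census. The `max_subgraphs` guard turns a run that would exhaust memory
  into a clean, classed error (exit code 3 from the command line).
* **Extension from every node.** Each newly recorded subgraph is extended by
  one absent edge incident to *any* of its current nodes. Extending only from
  the endpoints of the last-added edge — the natural reading of an anchored
  recursion — would constrain every subgraph to be buildable as a chain of
  pairwise-adjacent edges starting at the seed, and such an ordering does not
  always exist: a four-edge path whose earliest timestamp sits on an interior
  edge has no such chain, yet it is a perfectly valid occurrence. Extending
  from all nodes restores completeness; the visited set keeps counting
  exact. The test suite pins this case explicitly and, more broadly, checks
  the engine against the brute-force counter on hundreds of random graphs.

## Canonical labeling

Standardization alone does not identify a motif: relabelings of the same
structure must collapse to one key. `canonical_form()` orders nodes by degree
(descending, counting parallel edges individually), refines ties by each
node's sorted list of incident (rank, direction) pairs, and then iterates the
refinement against neighbor colors to a stable partition. The tempting final
tie-break — compare adjacency lists ordered by timestamp and then by
destination node — is circular as a definition (destination order presupposes
a node order), so it is used only as a refinement heuristic.
Canonicity is then *guaranteed* by exhaustive search: over every node
ordering consistent with the stable partition, the motif is serialized as
positional adjacency records — `(n0,1,n1)` with each edge emitted from both
endpoints, plus an `o`/`i` tag when directed — and the lexicographically
smallest serialization wins. Motifs have at most `k` nodes, so the factorial
search within refinement cells is cheap; *true twin* nodes (identical
concrete incidence records, hence swappable by an automorphism) are kept in a
fixed relative order so that, e.g., a hub broadcasting to many leaves
simultaneously does not trigger a factorial blow-up. Extremely symmetric
motifs beyond one million residual orderings raise an error rather than
silently degrade; none of the motif scales this package targets approach
that.

The labeling is verified two ways: the two-edge wedge must serialize to a
frozen reference string under all six of its relabelings, and over
the full universe of motifs with ≤ 4 nodes, ≤ 4 edges and ranks in {1, 2, 3}
(both directednesses, ~44k labeled motifs), canonical-string equality must
coincide exactly with the existence of a rank- and direction-preserving
bijection decided by a brute-force permutation oracle.

## The brute-force oracle and the synthetic generator

`brute_force_motif_counts()` enumerates *every* edge subset of size
`1..l` (refusing when `choose(|E|, l) > 1e7`), filters by connectivity of the
undirected skeleton, node count and span, and tallies canonical keys. It
shares only the canonical-labeling module with the engine — which is itself
verified independently, as above — so agreement between the two is a genuine
two-route check of the enumeration logic.

`generate_random_temporal_graph()` draws `n_edges` distinct `(u, v, t)`
triples uniformly without replacement, with integer timestamps on
`[0, t_max]`. It emulates the combinatorial structure the counting problem
cares about — multi-edges, simultaneous events on different pairs, windows
that cut across the timeline — under a fixed seed, and deliberately nothing
else: real contact networks have heavy-tailed activity, repeated bursts on
the same pair and diurnal rhythm, none of which affect the *correctness* of
an exact census, only its cost profile. Passing the randomized suites
therefore certifies counting correctness, not performance on any particular
real network.

Default study conditions used by the randomized correctness suites: 200
seeded graphs (100 directed, 100 undirected) with 4–12 nodes, 5–25 edges and
integer timestamps in [0, 30], crossed with the parameter grid
`delta ∈ {5, 10, ∞} × k ∈ {3, 4, 5} × l ∈ {2..6}`; the census maps must be
*exactly* equal between engine and oracle on every combination. These sizes
keep the brute-force side exhaustive (the oracle is the bottleneck, at
`choose(25, 6) ≈ 1.8e5` subsets per graph) while covering tied timestamps,
saturated node bounds and windows both binding and vacuous.

## Parameters, numerical choices, degenerate inputs

* `delta` (timestamp units, inclusive): the span bound. `Inf` disables the
  window. Comparisons are exact floating-point comparisons; integer
  timestamps are recommended and are what the edge-list reader produces for
  integer input.
* `k ≥ 2`, `l ≥ 1`: motif size bounds. Counts grow combinatorially in both;
  the visited set is the memory bound to watch, hence `max_subgraphs`.
* Window as a multiple of resolution: `resolution()` is the minimum positive
  gap between consecutive distinct timestamps, and the CLI's `--delta-mult R`
  sets `delta = R × resolution`, the conventional way to compare networks
  with different clock units. A graph with a single distinct timestamp has no
  resolution and `--delta-mult` errors on it.
* Duplicate input triples are collapsed (with a warning) rather than fatal,
  so real-world exports parse; self-loop lines are skipped with a warning.
* Census output is deterministic: rows sorted by count descending, ties by
  canonical form in byte (C-locale radix) order; the TSV writer and the CLI
  emit byte-identical files for identical inputs regardless of node naming
  or edge order.
* The summary triple (`n`, `Max`, `AVG`) reports the mean count rounded to
  the nearest integer on the CLI, matching the integer convention of census
  tables; the unrounded mean is logged and returned by `census_summary()`.

## Limitations

* The exact census stores one key per distinct subgraph; dense targets with
  large `l` exhaust memory by design — use `max_subgraphs` for a clean abort,
  or reduce `delta`, `k`, `l`. No sampling or approximate mode is provided.
* Canonical labeling is motif-scale only (guarded); it is not a general graph
  canonizer.
* Timestamps are compared exactly; irregular floating-point timestamps should
  be quantized by the caller if equality of "simultaneous" events matters.
* Edges model instantaneous interactions; durations, node/edge attributes and
  significance testing against null models are out of scope.
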
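#' Construct a temporal motif
#'
#' A temporal motif is a connected temporal graph in standardized form: edge
#' timestamps are ranks starting at 1, and the sorted distinct ranks are
#' consecutive (1, 2, ...). Equal ranks encode simultaneous events, which are
#' only allowed on different node pairs (different ordered pairs when
#' directed).
#'
#' @param source,dest node identifiers, one pair per edge.
#' @param rank integer ranks (>= 1), one per edge.
#' @param directed logical.
#' @return An object of class `temporal_motif`: a list with elements `nodes`,
#'   `edges` (data frame `source`, `dest`, `rank`) and `directed`.
#' @seealso [standardize_timestamps()], [canonical_form()]
#' @export
temporal_motif <- function(source, dest, rank, directed = FALSE) {
  source <- as.character(source)
  dest <- as.character(dest)
  rank <- as.integer(rank)
  m <- length(source)
  if (length(dest) != m || length(rank) != m) {
    stop("source, dest and rank must have equal length")
  }
  if (m == 0L) stop("a motif must have at least one edge")
  if (any(source == dest)) stop("self-loops are not allowed")
  if (anyNA(rank) || any(rank < 1L)) stop("ranks must be integers >= 1")
  r <- sort(unique(rank))
  if (!identical(r, seq_len(max(rank)))) {
    stop("ranks must start at 1 and be consecutive")
  }
  if (anyDuplicated(edge_triple_key(source, dest, rank, directed))) {
    stop("two edges share the same node pair and rank")
  }
  nodes <- unique(c(rbind(source, dest)))
  if (!is_connected_edges(match(source, nodes), match(dest, nodes),
                          length(nodes))) {
    stop("a motif must be connected")
  }
  structure(
    list(
      nodes = nodes,
      edges = data.frame(source = source, dest = dest, rank = rank,
                         stringsAsFactors = FALSE),
      directed = directed
    ),
    class = "temporal_motif"
  )
}

# connectivity of the undirected skeleton, by label propagation
is_connected_edges <- function(src, dst, n_nodes) {
  comp <- seq_len(n_nodes)
  repeat {
    lo <- pmin(comp[src], comp[dst])
    changed <- FALSE
    for (i in seq_along(src)) {
      if (comp[src[i]] != lo[i] || comp[dst[i]] != lo[i]) {
        comp[comp == comp[src[i]] | comp == comp[dst[i]]] <- lo[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(comp)) == 1L
}

#' Standardize timestamps into motif ranks
#'
#' Replaces the timestamps of a connected occurrence subgraph by the ranks of
#' their values: the distinct timestamps, sorted ascending, receive ranks
#' 1, 2, ...; ties (simultaneous events) share a rank. Topology and edge
#' directions are unchanged. The operation is idempotent: applied to a motif
#' it returns the same ranks.
#'
#' @param x a [temporal_graph()], a [temporal_motif()], or a data frame with
#'   columns `source`, `dest` and `timestamp`.
#' @param ... passed to methods.
#' @return A [temporal_motif()].
#' @examples
#' g <- temporal_graph(c("a", "b", "c", "a"), c("b", "c", "d", "d"),
#'                     c(5, 9, 9, 14))
#' standardize_timestamps(g)$edges$rank  # 1 2 2 3
#' @export
standardize_timestamps <- function(x, ...) UseMethod("standardize_timestamps")

#' @param edge_ids for the `temporal_graph` method, the 0-based `edge_id`s of
#'   the occurrence subgraph to standardize; `NULL` takes every edge.
#' @rdname standardize_timestamps
#' @export
standardize_timestamps.temporal_graph <- function(x, edge_ids = NULL, ...) {
  e <- x$edges
  if (!is.null(edge_ids)) {
    idx <- match(edge_ids, e$edge_id)
    if (anyNA(idx)) stop("unknown edge_id")
    e <- e[idx, , drop = FALSE]
  }
  if (nrow(e) == 0L) stop("cannot standardize an empty subgraph")
  rank <- match(e$timestamp, sort(unique(e$timestamp)))
  temporal_motif(e$source, e$dest, rank, directed = x$directed)
}

#' @rdname standardize_timestamps
#' @export
standardize_timestamps.temporal_motif <- function(x, ...) {
  rank <- match(x$edges$rank, sort(unique(x$edges$rank)))
  temporal_motif(x$edges$source, x$edges$dest, rank, directed = x$directed)
}

#' @rdname standardize_timestamps
#' @export
standardize_timestamps.data.frame <- function(x, directed = FALSE, ...) {
  stopifnot(all(c("source", "dest", "timestamp") %in% names(x)))
  if (nrow(x) == 0L) stop("cannot standardize an empty subgraph")
  rank <- match(x$timestamp, sort(unique(x$timestamp)))
  temporal_motif(x$source, x$dest, rank, directed = directed)
}

#' Canonical form of a temporal motif
#'
#' Computes an isomorphism-invariant string key: two motifs map to the same
#' string exactly when a node bijection preserving edges, directions and ranks
#' relates them. Nodes are ordered by degree (descending, counting parallel
#' edges individually) and then by their sorted incident (rank, direction)
#' lists; ties left open by this refinement are resolved by an exhaustive
#' lexicographic-minimum search over the consistent orderings, so the key is a
#' complete invariant at motif scale. In the string, nodes are positional
#' labels `n0, n1, ...` and each edge appears once from each endpoint as a
#' record `(self,rank,neighbor)`, with an `o`/`i` tag appended for directed
#' motifs; records are joined with `;`.
#'
#' @param motif a [temporal_motif()].
#' @return A single string.
#' @examples
#' m <- temporal_motif(c("a", "a"), c("b", "c"), c(1, 2))
#' canonical_form(m)  # "(n0,1,n1);(n0,2,n2);(n1,1,n0);(n2,2,n0)"
#' @export
canonical_form <- function(motif) {
  stopifnot(inherits(motif, "temporal_motif"))
  u <- match(motif$edges$source, motif$nodes)
  v <- match(motif$edges$dest, motif$nodes)
  cpp_canonical_form(u, v, motif$edges$rank, length(motif$nodes),
                     motif$directed)
}

#' @export
print.temporal_motif <- function(x, ...) {
  cat(sprintf("temporal_motif: %d nodes, %d edges (%s)\n",
              length(x$nodes), nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  arrow <- if (x$directed) "->" else "--"
  cat(sprintf("  %s %s %s @ %d\n", x$edges$source, arrow, x$edges$dest,
              x$edges$rank), sep = "")
  invisible(x)
}
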
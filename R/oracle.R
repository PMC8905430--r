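#' Brute-force reference motif counts
#'
#' Independent reference implementation of the motif census: enumerates every
#' edge subset of size 1..`l`, keeps those whose induced graph is connected
#' (on the undirected skeleton), has at most `k` nodes, and spans at most
#' `delta` in time, then standardizes, canonizes and tallies. It shares no
#' code with the seed-and-extend engine apart from the canonical-labeling
#' module, and is meant as a correctness oracle on small graphs, not for
#' production use.
#'
#' @inheritParams count_temporal_motifs
#' @param .table a precomputed [subset_motif_table()] for `g` with
#'   `l_max >= l`, to amortize the subset enumeration over repeated calls with
#'   different parameters. Computed on the fly when `NULL`.
#' @return A `motif_counts` object (same shape as
#'   [count_temporal_motifs()]).
#' @export
brute_force_motif_counts <- function(g, delta, k, l, .table = NULL) {
  stopifnot(inherits(g, "temporal_graph"))
  check_search_params(delta, k, l)
  m <- nrow(g$edges)
  if (choose(m, min(l, m)) > 1e7) {
    stop("refusing brute-force enumeration: choose(|E|, l) exceeds 1e7")
  }
  if (is.null(.table)) {
    .table <- subset_motif_table(g, min(l, m))
  } else if (attr(.table, "l_max") < min(l, m)) {
    stop(".table was built with a smaller l_max than requested")
  }
  keep <- .table$n_edges <= l & .table$n_nodes <= k & .table$span <= delta
  tab <- table(.table$canonical_form[keep])
  new_motif_counts(names(tab), as.numeric(tab),
                   params = list(delta = delta, k = as.integer(k),
                                 l = as.integer(l), directed = g$directed),
                   n_subgraphs = sum(keep))
}

#' Enumerate connected edge subsets with their motif keys
#'
#' Support table for [brute_force_motif_counts()]: one row per connected edge
#' subset of `g` with at most `l_max` edges, holding the subset size, the
#' number of covered nodes, the timestamp span, and the canonical form of the
#' standardized motif. Filtering the rows by `n_edges <= l`, `n_nodes <= k`
#' and `span <= delta` yields the census for any parameter triple.
#'
#' @param g a [temporal_graph()].
#' @param l_max largest subset size to enumerate.
#' @return A data frame with columns `n_edges`, `n_nodes`, `span`,
#'   `canonical_form`.
#' @export
subset_motif_table <- function(g, l_max) {
  m <- nrow(g$edges)
  l_max <- min(l_max, m)
  parts <- vector("list", l_max)
  for (j in seq_len(l_max)) {
    cm <- utils::combn(m, j)
    scr <- cpp_screen_subsets(g$src_idx, g$dst_idx, g$edges$timestamp, cm)
    keep <- scr$connected
    if (!any(keep)) next
    cm <- cm[, keep, drop = FALSE]
    keys <- cpp_motif_keys(g$src_idx, g$dst_idx, g$edges$timestamp,
                           asplit(cm, 2L), g$directed)
    parts[[j]] <- data.frame(
      n_edges = j,
      n_nodes = scr$n_nodes[keep],
      span = scr$span[keep],
      canonical_form = as.character(keys),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
  attr(out, "l_max") <- l_max
  out
}

#' Generate a seeded random temporal graph
#'
#' Samples `n_edges` distinct triples (u, v, t) uniformly without replacement
#' from all pairs of distinct nodes and integer timestamps in `[0, t_max]`
#' (unordered pairs when undirected). The same seed always yields the same
#' graph; the caller's random-number state is left untouched.
#'
#' @param n_nodes number of nodes (>= 2); all appear in the graph, possibly
#'   isolated.
#' @param n_edges number of edges (>= 1); must not exceed the number of
#'   distinct triples available.
#' @param t_max largest timestamp (integer >= 0).
#' @param directed logical.
#' @param seed integer seed.
#' @return A [temporal_graph()] with nodes `"v1" ... "v<n_nodes>"`.
#' @examples
#' g <- generate_random_temporal_graph(6, 10, t_max = 30, seed = 1)
#' @export
generate_random_temporal_graph <- function(n_nodes, n_edges, t_max,
                                           directed = FALSE, seed) {
  stopifnot(n_nodes >= 2, n_edges >= 1, t_max >= 0)
  if (directed) {
    pairs <- expand.grid(u = seq_len(n_nodes), v = seq_len(n_nodes))
    pairs <- pairs[pairs$u != pairs$v, , drop = FALSE]
  } else {
    cm <- utils::combn(n_nodes, 2L)
    pairs <- data.frame(u = cm[1L, ], v = cm[2L, ])
  }
  n_pairs <- nrow(pairs)
  n_triples <- n_pairs * (t_max + 1)
  if (n_edges > n_triples) {
    stop(sprintf("infeasible: %d edges requested but only %d distinct triples exist",
                 n_edges, n_triples))
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  idx <- sample.int(n_triples, n_edges)

  pair_id <- (idx - 1L) %/% (t_max + 1L) + 1L
  t <- (idx - 1L) %% (t_max + 1L)
  temporal_graph(paste0("v", pairs$u[pair_id]), paste0("v", pairs$v[pair_id]),
                 t, directed = directed,
                 nodes = paste0("v", seq_len(n_nodes)))
}

#' Enumerate the universe of small temporal motifs
#'
#' Constructs every connected temporal motif with at most `k` nodes, at most
#' `l` edges and ranks in `1..max_rank` (subject to the motif invariants:
#' ranks start at 1 and are consecutive; no two edges share a node pair and a
#' rank), and returns the set of distinct canonical forms. Used to verify that
#' the canonical labeling is a complete invariant at small scale.
#'
#' @param k maximum nodes (2..4).
#' @param l maximum edges (1..4).
#' @param directed logical.
#' @param max_rank largest rank considered (default 3).
#' @return A sorted character vector of distinct canonical forms.
#' @export
enumerate_motif_universe <- function(k, l, directed = FALSE, max_rank = 3L) {
  uni <- motif_universe_table(k, l, directed, max_rank)
  sort(unique(uni$canonical_form), method = "radix")
}

# Full labeled universe: one row per valid labeled motif, with the candidate
# edges (as indices into the combo table) retained so tests can re-derive the
# motif. Guarded to motif scale.
motif_universe_table <- function(k, l, directed = FALSE, max_rank = 3L) {
  stopifnot(k >= 2, k <= 4, l >= 1, l <= 4, max_rank >= 1)
  if (directed) {
    pr <- expand.grid(u = seq_len(k), v = seq_len(k))
    pr <- pr[pr$u != pr$v, , drop = FALSE]
  } else {
    cm <- utils::combn(k, 2L)
    pr <- data.frame(u = cm[1L, ], v = cm[2L, ])
  }
  combos <- expand.grid(pair = seq_len(nrow(pr)),
                        rank = seq_len(min(max_rank, l)))
  csrc <- pr$u[combos$pair]
  cdst <- pr$v[combos$pair]
  crank <- combos$rank
  nc <- nrow(combos)

  rows <- list()
  for (j in seq_len(min(l, nc))) {
    cm <- utils::combn(nc, j)
    # ranks must start at 1 and be consecutive
    rk <- matrix(crank[cm], nrow = j)
    valid <- apply(rk, 2L, function(r) {
      u <- sort(unique(r))
      identical(u, seq_along(u))
    })
    cm <- cm[, valid, drop = FALSE]
    if (ncol(cm) == 0L) next
    scr <- cpp_screen_subsets(csrc, cdst, as.numeric(crank), cm)
    cm <- cm[, scr$connected, drop = FALSE]
    if (ncol(cm) == 0L) next
    keys <- cpp_motif_keys(csrc, cdst, as.numeric(crank),
                           asplit(cm, 2L), directed)
    rows[[j]] <- data.frame(
      n_edges = j,
      canonical_form = as.character(keys),
      combo = I(asplit(cm, 2L)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "combos") <- data.frame(u = csrc, v = cdst, rank = crank)
  out
}
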
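# Shared test helpers: census comparison, permutation utilities, and an
# independent brute-force isomorphism key for motifs (used as the oracle
# against the canonical labeling).

counts_map <- function(x) {
  stats::setNames(x$count, x$canonical_form)[order(x$canonical_form,
                                                   method = "radix")]
}

expect_same_census <- function(a, b) {
  expect_identical(counts_map(a), counts_map(b))
}

# all permutations of 1..n, one per row
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  smaller <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[smaller], nrow(smaller)))
  }))
}

# Complete isomorphism invariant by exhaustive search over ALL node
# permutations of a naive edge-tuple encoding. Independent of the package's
# refinement-based canonical labeling.
brute_motif_key <- function(u, v, rank, directed) {
  nodes <- sort(unique(c(u, v)))
  ui <- match(u, nodes)
  vi <- match(v, nodes)
  p_all <- perms(length(nodes))
  best <- NULL
  for (r in seq_len(nrow(p_all))) {
    p <- p_all[r, ]
    a <- p[ui]
    b <- p[vi]
    if (!directed) {
      lo <- pmin(a, b)
      hi <- pmax(a, b)
      a <- lo
      b <- hi
    }
    key <- paste(sort(sprintf("%d.%d.%d", a, rank, b)), collapse = "|")
    if (is.null(best) || key < best) best <- key
  }
  best
}

# is there a rank/direction preserving bijection between two labeled motifs?
motifs_isomorphic <- function(m1, m2, directed) {
  identical(
    brute_motif_key(m1$u, m1$v, m1$rank, directed),
    brute_motif_key(m2$u, m2$v, m2$rank, directed)
  )
}

# node count and edge count encoded in a canonical string
canon_dims <- function(canon) {
  recs <- strsplit(canon, ";", fixed = TRUE)[[1L]]
  labels <- unlist(regmatches(recs, gregexpr("n[0-9]+", recs)))
  list(n_nodes = length(unique(labels)), n_edges = length(recs) %/% 2L)
}

# relabel nodes and shuffle edge order; the census must be unchanged
permuted_graph <- function(g, seed) {
  set.seed(seed)
  new_labels <- stats::setNames(
    paste0("w", sample(length(g$nodes))), g$nodes
  )
  ord <- sample(nrow(g$edges))
  temporal_graph(new_labels[g$edges$source[ord]],
                 new_labels[g$edges$dest[ord]],
                 g$edges$timestamp[ord],
                 directed = g$directed,
                 nodes = unname(new_labels))
}

write_edge_file <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
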
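test_that("timestamps standardize to dense ranks starting at 1", {
  g1 <- temporal_graph("u", "v", 7)
  expect_identical(standardize_timestamps(g1)$edges$rank, 1L)

  g2 <- temporal_graph(c("a", "b", "c", "a"), c("b", "c", "d", "d"),
                       c(5, 9, 9, 14))
  expect_identical(standardize_timestamps(g2)$edges$rank, c(1L, 2L, 2L, 3L))

  # simultaneous events on different pairs share rank 1
  g3 <- temporal_graph(c("a", "b"), c("b", "c"), c(3, 3))
  expect_identical(standardize_timestamps(g3)$edges$rank, c(1L, 1L))

  expect_error(standardize_timestamps(g2, edge_ids = integer()), "empty")
})

test_that("standardization is idempotent on motifs", {
  checked <- 0L
  for (s in 1:10) {
    dir <- s %% 2 == 0
    g <- generate_random_temporal_graph(5, 7, 6, directed = dir,
                                        seed = 200 + s)
    cm <- combn(nrow(g$edges), 3)
    scr <- temporalmotifs:::cpp_screen_subsets(g$src_idx, g$dst_idx,
                                               g$edges$timestamp, cm)
    for (i in which(scr$connected)[1:2]) {
      if (is.na(i)) next
      m <- standardize_timestamps(g, edge_ids = cm[, i] - 1L)
      m2 <- standardize_timestamps(m)
      expect_identical(m2$edges$rank, m$edges$rank)
      expect_identical(canonical_form(m2), canonical_form(m))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 10L)
})

test_that("motif invariants are enforced", {
  expect_error(temporal_motif("a", "b", 2), "start at 1")
  expect_error(temporal_motif(c("a", "b"), c("b", "c"), c(1, 3)),
               "consecutive")
  expect_error(temporal_motif(c("a", "a"), c("b", "b"), c(1, 1)),
               "same node pair and rank")
  expect_error(temporal_motif(c("a", "c"), c("b", "d"), c(1, 2)),
               "connected")
  # directed: opposite orientations may share a rank
  m <- temporal_motif(c("a", "b"), c("b", "a"), c(1, 1), directed = TRUE)
  expect_s3_class(m, "temporal_motif")
  expect_error(temporal_motif(c("a", "b"), c("b", "a"), c(1, 1)),
               "same node pair and rank")
})

test_that("canonical form is invariant under node relabeling", {
  m1 <- temporal_motif(c("a", "a"), c("b", "c"), c(1, 2))
  m2 <- temporal_motif(c("x", "x"), c("y", "z"), c(1, 2))
  expect_identical(canonical_form(m1), canonical_form(m2))
  expect_identical(canonical_form(m1),
                   "(n0,1,n1);(n0,2,n2);(n1,1,n0);(n2,2,n0)")
})

test_that("directed rank order distinguishes non-isomorphic paths", {
  # a->c then c->b versus the same topology traversed in reverse rank order:
  # brute-force over all 3! bijections confirms no isomorphism relates them
  m1 <- list(u = c("a", "c"), v = c("c", "b"), rank = c(1L, 2L))
  m2 <- list(u = c("a", "c"), v = c("c", "b"), rank = c(2L, 1L))
  expect_false(motifs_isomorphic(m1, m2, directed = TRUE))
  c1 <- canonical_form(temporal_motif(m1$u, m1$v, m1$rank, directed = TRUE))
  c2 <- canonical_form(temporal_motif(m2$u, m2$v, m2$rank, directed = TRUE))
  expect_false(identical(c1, c2))
})

test_that("canonical form ignores edge-list order", {
  checked <- 0L
  for (s in 1:20) {
    dir <- s %% 2 == 0
    g <- generate_random_temporal_graph(6, 8, 5, directed = dir,
                                        seed = 300 + s)
    cm <- combn(nrow(g$edges), 4)
    scr <- temporalmotifs:::cpp_screen_subsets(g$src_idx, g$dst_idx,
                                               g$edges$timestamp, cm)
    idx <- which(scr$connected)
    if (length(idx) == 0) next
    sub <- g$edges[cm[, idx[1L]], , drop = FALSE]
    ref <- canonical_form(standardize_timestamps(sub, directed = dir))
    set.seed(s)
    for (rep in 1:3) {
      shuffled <- sub[sample(nrow(sub)), , drop = FALSE]
      expect_identical(
        canonical_form(standardize_timestamps(shuffled, directed = dir)),
        ref
      )
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 20L)
})

test_that("the batch motif keys match standardize + canonize", {
  for (s in 1:10) {
    dir <- s %% 2 == 0
    g <- generate_random_temporal_graph(6, 10, 8, directed = dir,
                                        seed = 400 + s)
    m <- nrow(g$edges)
    cm <- combn(m, 3)
    scr <- temporalmotifs:::cpp_screen_subsets(g$src_idx, g$dst_idx,
                                               g$edges$timestamp, cm)
    cm <- cm[, scr$connected, drop = FALSE]
    if (ncol(cm) == 0) next
    keys <- temporalmotifs:::cpp_motif_keys(g$src_idx, g$dst_idx,
                                            g$edges$timestamp,
                                            asplit(cm, 2), dir)
    ref <- vapply(seq_len(ncol(cm)), function(i) {
      canonical_form(standardize_timestamps(g, edge_ids = cm[, i] - 1L))
    }, "")
    expect_identical(as.character(keys), ref)
  }
})
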
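test_that("window bookkeeping follows lambda = delta - maxTime + minTime", {
  s <- update_bounds(window_state(5), delta = 10)
  expect_identical(s$maxTime, 5)
  expect_identical(s$lambda, 10)

  s <- update_bounds(window_state(c(5, 9)), delta = 10)
  expect_identical(s$maxTime, 9)
  expect_identical(s$lambda, 6)

  s <- update_bounds(window_state(c(5, 15)), delta = 10)
  expect_identical(s$maxTime, 15)
  expect_identical(s$lambda, 0)
  # algebraic identity: the admission interval is constant per seed
  expect_identical(s$maxTime + s$lambda, s$minTime + 10)

  expect_error(update_bounds(window_state(numeric()), 10), "non-empty")
})

test_that("the smallest instance counts one single-edge motif", {
  g <- temporal_graph("u", "v", 5)
  res <- count_temporal_motifs(g, delta = 0, k = 2, l = 1)
  expect_identical(nrow(res), 1L)
  expect_identical(res$count, 1)
})

test_that("the delta window excludes distant co-occurrences", {
  g <- temporal_graph(c("a", "b"), c("b", "c"), c(0, 100))
  res <- count_temporal_motifs(g, delta = 10, k = 3, l = 2)
  # two single edges, no wedge: span 100 > delta
  expect_identical(nrow(res), 1L)
  expect_identical(res$count, 2)
  expect_same_census(res, brute_force_motif_counts(g, 10, 3, 2))
})

test_that("directed out-star counts follow the binomial closed form", {
  g <- temporal_graph(rep("h", 4), paste0("x", 1:4), 1:4, directed = TRUE)
  res <- count_temporal_motifs(g, delta = 10, k = 5, l = 3)
  expect_identical(sort(res$count), sort(c(choose(4, 1), choose(4, 2),
                                           choose(4, 3))))
  expect_same_census(res, brute_force_motif_counts(g, 10, 5, 3))
})

test_that("window admission is inclusive and anchored at the seed", {
  # triangle a-b@5, b-c@9, a-c@14: with delta = 10 every pair and the
  # triangle fit (max span 9 <= 10); with delta = 8 the subgraphs containing
  # both @5 and @14 are excluded (span 9 > 8)
  g <- temporal_graph(c("a", "b", "a"), c("b", "c", "c"), c(5, 9, 14))
  r10 <- count_temporal_motifs(g, delta = 10, k = 3, l = 3)
  expect_identical(sum(r10$count), 3 + 3 + 1)
  r8 <- count_temporal_motifs(g, delta = 8, k = 3, l = 3)
  # lost: wedge {5,14} and the triangle
  expect_identical(sum(r8$count), 3 + 2)
  expect_same_census(r10, brute_force_motif_counts(g, 10, 3, 3))
  expect_same_census(r8, brute_force_motif_counts(g, 8, 3, 3))
  # boundary: span exactly delta is admitted
  r9 <- count_temporal_motifs(g, delta = 9, k = 3, l = 3)
  expect_identical(sum(r9$count), 3 + 3 + 1)
})

test_that("subgraphs reachable only through non-chain growth are found", {
  # 4-edge path with its minimum timestamp on an interior edge: the full
  # path cannot be grown as a chain of adjacent edges from the seed, so it
  # exercises extension from every node of the current subgraph
  g <- temporal_graph(paste0("v", 1:4), paste0("v", 2:5), c(5, 1, 6, 7))
  res <- count_temporal_motifs(g, delta = Inf, k = 5, l = 4)
  orc <- brute_force_motif_counts(g, Inf, 5, 4)
  expect_same_census(res, orc)
  # the 4-edge path occurs exactly once
  four <- res[vapply(res$canonical_form,
                     function(cf) canon_dims(cf)$n_edges == 4L, TRUE), ]
  expect_identical(nrow(four), 1L)
  expect_identical(four$count, 1)
})

test_that("a subgraph with a tied minimum timestamp is counted once", {
  g <- temporal_graph(c("a", "b"), c("b", "c"), c(5, 5))
  res <- count_temporal_motifs(g, delta = 10, k = 3, l = 2)
  m <- counts_map(res)
  expect_identical(unname(m[vapply(names(m), function(cf)
    canon_dims(cf)$n_edges == 2L, TRUE)]), 1)
  expect_same_census(res, brute_force_motif_counts(g, 10, 3, 2))
})

test_that("single-edge motif count always equals the number of edges", {
  for (s in 1:8) {
    dir <- s %% 2 == 0
    g <- generate_random_temporal_graph(7, 12, 10, directed = dir,
                                        seed = 500 + s)
    res <- count_temporal_motifs(g, delta = 3, k = 3, l = 2)
    one <- res$count[vapply(res$canonical_form, function(cf)
      canon_dims(cf)$n_edges == 1L, TRUE)]
    expect_identical(sum(one), as.numeric(nrow(g$edges)))
  }
})

test_that("counts are monotone in delta and consistent under restriction", {
  for (s in 1:6) {
    dir <- s %% 2 == 0
    g <- generate_random_temporal_graph(8, 14, 12, directed = dir,
                                        seed = 600 + s)
    maps <- lapply(c(3, 6, Inf), function(d)
      counts_map(count_temporal_motifs(g, d, 4, 4)))
    for (i in 1:2) {
      small <- maps[[i]]
      big <- maps[[i + 1L]]
      expect_true(all(names(small) %in% names(big)))
      expect_true(all(small <= big[names(small)]))
    }
    # restriction: the (k', l') census is the (k, l) census filtered
    full <- counts_map(count_temporal_motifs(g, 6, 4, 4))
    dims <- lapply(names(full), canon_dims)
    keep <- vapply(dims, function(d) d$n_nodes <= 3 && d$n_edges <= 2, TRUE)
    expect_identical(full[keep],
                     counts_map(count_temporal_motifs(g, 6, 3, 2)))
  }
})

test_that("the census is invariant under relabeling and edge shuffling", {
  for (s in 1:6) {
    dir <- s %% 2 == 0
    g <- generate_random_temporal_graph(8, 14, 12, directed = dir,
                                        seed = 700 + s)
    g2 <- permuted_graph(g, seed = s)
    a <- count_temporal_motifs(g, 5, 4, 3)
    b <- count_temporal_motifs(g2, 5, 4, 3)
    expect_same_census(a, b)
    # byte-identical serialized output
    fa <- tempfile()
    fb <- tempfile()
    write_motif_counts(a, fa)
    write_motif_counts(b, fb)
    expect_identical(readLines(fa), readLines(fb))
  }
})

test_that("the subgraph guard aborts with a classed error", {
  g <- generate_random_temporal_graph(8, 20, 10, seed = 1)
  expect_error(
    count_temporal_motifs(g, Inf, 5, 5, max_subgraphs = 50),
    class = "temporalmotifs_subgraph_limit"
  )
  # generous guard does not trip
  res <- count_temporal_motifs(g, Inf, 3, 2, max_subgraphs = 1e6)
  expect_s3_class(res, "motif_counts")
})

test_that("search parameters are validated", {
  g <- temporal_graph("a", "b", 1)
  expect_error(count_temporal_motifs(g, -1, 3, 2), "delta")
  expect_error(count_temporal_motifs(g, 1, 1, 2), "k must")
  expect_error(count_temporal_motifs(g, 1, 3, 0), "l must")
})

test_that("census summaries aggregate the count map", {
  g <- temporal_graph(c("a", "b", "d"), c("b", "c", "e"), c(1, 2, 100))
  res <- count_temporal_motifs(g, delta = 1, k = 3, l = 2)
  s <- census_summary(res)
  expect_identical(s$n_distinct, 2L)
  expect_identical(s$max_count, 3)
  expect_identical(s$avg_count * s$n_distinct, sum(res$count))
})
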
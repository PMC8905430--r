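#' Count temporal motifs in a delta window
#'
#' Enumerates every connected subgraph of `g` with at most `k` nodes, at most
#' `l` edges and a timestamp span (max - min) of at most `delta`, and tallies
#' each one under the canonical form of its standardized motif. Every edge of
#' the target acts as a seed: a subgraph is grown from its minimum-timestamp
#' edge, one incident edge at a time, admitting only timestamps in
#' `[minTime, minTime + delta]`; a global visited set keyed by the sorted
#' edge-id tuple guarantees that each subgraph is counted exactly once, even
#' when its minimum timestamp is shared by several edges. The result is
#' independent of edge input order and node naming.
#'
#' @param g a [temporal_graph()].
#' @param delta maximum timestamp span, inclusive; `Inf` disables the window.
#' @param k maximum number of motif nodes (>= 2).
#' @param l maximum number of motif edges (>= 1).
#' @param max_subgraphs abort with an error of class
#'   `temporalmotifs_subgraph_limit` once more than this many distinct
#'   subgraphs have been visited. The visited set holds one key per subgraph,
#'   so memory grows with the number of occurrences; the guard turns an
#'   out-of-memory run into a clean diagnostic.
#' @return An object of class `motif_counts`: a data frame with columns
#'   `canonical_form` and `count`, ordered by decreasing count and then by
#'   canonical form (byte order), with the search parameters and the number of
#'   visited subgraphs in attributes `params` and `n_subgraphs`.
#' @seealso [brute_force_motif_counts()] for the independent reference
#'   implementation, [census_summary()], [write_motif_counts()].
#' @examples
#' g <- temporal_graph(c("a", "b"), c("b", "c"), c(5, 9))
#' count_temporal_motifs(g, delta = 10, k = 3, l = 2)
#' @export
count_temporal_motifs <- function(g, delta, k, l, max_subgraphs = Inf) {
  stopifnot(inherits(g, "temporal_graph"))
  check_search_params(delta, k, l)
  res <- tryCatch(
    cpp_count_motifs(g$src_idx, g$dst_idx, g$edges$timestamp,
                     length(g$nodes), g$directed, delta, as.integer(k),
                     as.integer(l), max_subgraphs),
    error = function(e) {
      if (grepl("subgraph limit exceeded", conditionMessage(e), fixed = TRUE)) {
        stop(structure(
          class = c("temporalmotifs_subgraph_limit", "error", "condition"),
          list(message = conditionMessage(e), call = sys.call(-1L))
        ))
      }
      stop(e)
    }
  )
  new_motif_counts(res$canonical_form, res$count,
                   params = list(delta = delta, k = as.integer(k),
                                 l = as.integer(l), directed = g$directed),
                   n_subgraphs = res$n_subgraphs)
}

check_search_params <- function(delta, k, l) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0) {
    stop("delta must be a single number >= 0")
  }
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 2 || k != floor(k)) {
    stop("k must be a single integer >= 2")
  }
  if (!is.numeric(l) || length(l) != 1L || is.na(l) || l < 1 || l != floor(l)) {
    stop("l must be a single integer >= 1")
  }
  invisible(TRUE)
}

# shared constructor: deterministic row order (count desc, canonical form
# ascending in byte order)
new_motif_counts <- function(canonical_form, count, params, n_subgraphs) {
  ord <- order(-count, canonical_form, method = "radix")
  out <- data.frame(canonical_form = as.character(canonical_form)[ord],
                    count = as.numeric(count)[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, params = params, n_subgraphs = n_subgraphs,
            class = c("motif_counts", "data.frame"))
}

#' @export
print.motif_counts <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("motif_counts: %d distinct motifs, %s occurrences (delta = %s, k = %d, l = %d)\n",
              nrow(x), format(sum(x$count), big.mark = ","),
              format(p$delta), p$k, p$l))
  print.data.frame(x, ...)
  invisible(x)
}

#' Census summary statistics
#'
#' Summarizes a motif census by the number of distinct motifs, the number of
#' occurrences of the most frequent motif, and the arithmetic mean number of
#' occurrences per distinct motif.
#'
#' @param x a `motif_counts` object.
#' @return A list with elements `n_distinct`, `max_count` and `avg_count`
#'   (unrounded; `avg_count * n_distinct` equals the total number of
#'   occurrences).
#' @export
census_summary <- function(x) {
  stopifnot(inherits(x, "motif_counts"))
  list(
    n_distinct = nrow(x),
    max_count = max(x$count),
    avg_count = mean(x$count)
  )
}

#' Write motif counts as TSV
#'
#' Writes a header line `canonical_form<TAB>count` followed by one row per
#' motif, in the deterministic order of the `motif_counts` object (count
#' descending, ties by canonical form ascending).
#'
#' @param x a `motif_counts` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_motif_counts <- function(x, path) {
  stopifnot(inherits(x, "motif_counts"))
  lines <- c("canonical_form\tcount",
             sprintf("%s\t%.0f", x$canonical_form, x$count))
  writeLines(lines, path)
  invisible(path)
}

#' Update the window bookkeeping of a growing subgraph
#'
#' During the search, each partial subgraph carries its timestamp multiset,
#' the seed timestamp `minTime`, the running maximum `maxTime`, and the
#' remaining slack `lambda = delta - maxTime + minTime`, i.e. how much the
#' window may still stretch without exceeding `delta`. Since
#' `maxTime + lambda = minTime + delta` is constant per seed, the engine tests
#' admission directly against `[minTime, minTime + delta]`; this function
#' maintains the explicit state for inspection and testing.
#'
#' @param state a list with elements `timestampSet` (non-empty numeric
#'   multiset) and `minTime`; see [window_state()].
#' @param delta the window width.
#' @return The state with `maxTime` and `lambda` recomputed.
#' @examples
#' update_bounds(window_state(c(5, 9)), delta = 10)$lambda  # 6
#' @export
update_bounds <- function(state, delta) {
  if (length(state$timestampSet) == 0L) {
    stop("timestampSet must be non-empty")
  }
  state$maxTime <- max(state$timestampSet)
  state$lambda <- delta - state$maxTime + state$minTime
  state
}

#' @param timestamps numeric multiset of the subgraph's edge timestamps.
#' @param min_time the seed timestamp; defaults to the minimum.
#' @rdname update_bounds
#' @export
window_state <- function(timestamps,
                         min_time = if (length(timestamps)) min(timestamps)
                                    else NA_real_) {
  list(timestampSet = timestamps, minTime = min_time,
       maxTime = NA_real_, lambda = NA_real_)
}
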
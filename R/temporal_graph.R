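#' Construct a temporal graph
#'
#' A temporal graph is a multigraph whose edges carry numeric timestamps:
#' several edges may connect the same pair of nodes provided their timestamps
#' differ. Edges are stored once per (source, dest, timestamp) triple -- for
#' undirected graphs once per unordered pair and timestamp -- and indexed from
#' both endpoints, so an edge id identifies an interaction unambiguously.
#'
#' @param source,dest character (or coercible) node identifiers, one pair per
#'   edge. Self-loops are not allowed.
#' @param timestamp numeric timestamps, one per edge. Integer timestamps are
#'   recommended; any finite numeric value is accepted and compared exactly.
#' @param directed logical; if `FALSE` (default) the pair `{source, dest}` is
#'   unordered and a triple duplicating a prior one in reversed orientation is
#'   rejected as a duplicate.
#' @param nodes optional character vector of node identifiers; must contain
#'   every edge endpoint. Allows isolated nodes.
#'
#' @return An object of class `temporal_graph`: a list with elements `nodes`
#'   (character), `edges` (data frame with columns `edge_id` -- 0-based,
#'   in input order -- `source`, `dest`, `timestamp`), `directed`, and
#'   `incidence` (named list mapping each node to the ascending edge ids
#'   incident to it).
#' @seealso [read_temporal_edge_list()], [incident_edges()],
#'   [count_temporal_motifs()]
#' @examples
#' g <- temporal_graph(c("a", "b"), c("b", "c"), c(5, 9))
#' incident_edges(g, "b")
#' @export
temporal_graph <- function(source, dest, timestamp, directed = FALSE,
                           nodes = NULL) {
  source <- as.character(source)
  dest <- as.character(dest)
  timestamp <- as.numeric(timestamp)
  m <- length(source)
  if (length(dest) != m || length(timestamp) != m) {
    stop("source, dest and timestamp must have equal length")
  }
  if (m == 0L) stop("no edges")
  if (anyNA(source) || anyNA(dest) || any(!is.finite(timestamp))) {
    stop("edge endpoints must be non-missing and timestamps finite")
  }
  if (any(source == dest)) stop("self-loops are not allowed")
  if (anyDuplicated(edge_triple_key(source, dest, timestamp, directed))) {
    stop("duplicate edge triples (same endpoints and timestamp)")
  }

  node_set <- unique(c(rbind(source, dest)))
  if (!is.null(nodes)) {
    nodes <- as.character(nodes)
    if (!all(node_set %in% nodes)) {
      stop("'nodes' must contain every edge endpoint")
    }
    node_set <- unique(nodes)
  }

  edges <- data.frame(
    edge_id = seq_len(m) - 1L,
    source = source,
    dest = dest,
    timestamp = timestamp,
    stringsAsFactors = FALSE
  )
  src_idx <- match(source, node_set)
  dst_idx <- match(dest, node_set)
  incidence <- lapply(seq_along(node_set), function(i) {
    sort(c(edges$edge_id[src_idx == i], edges$edge_id[dst_idx == i]))
  })
  names(incidence) <- node_set

  structure(
    list(
      nodes = node_set,
      edges = edges,
      directed = directed,
      incidence = incidence,
      src_idx = src_idx,
      dst_idx = dst_idx
    ),
    class = "temporal_graph"
  )
}

# key identifying an edge triple; unordered endpoints when undirected
edge_triple_key <- function(source, dest, timestamp, directed) {
  if (!directed) {
    lo <- pmin(source, dest)
    hi <- pmax(source, dest)
    source <- lo
    dest <- hi
  }
  paste(source, dest, format(timestamp, digits = 17L), sep = "\r")
}

#' Read a timestamped edge list
#'
#' Parses a plain-text edge list with one `source dest timestamp` record per
#' line, whitespace-separated, with `#`-prefixed comment lines and blank lines
#' ignored (the dialect used by common temporal-network repositories). Fields
#' beyond the third are ignored. Self-loop lines are skipped and duplicate
#' triples -- for undirected graphs, also a line repeating an earlier one in
#' reversed orientation -- are collapsed to a single edge; both are reported
#' with a warning.
#'
#' @param path path to the edge-list file.
#' @param directed logical; read the file as a directed graph?
#' @return A [temporal_graph()].
#' @examples
#' f <- tempfile()
#' writeLines(c("# comment", "a b 5", "b c 9"), f)
#' read_temporal_edge_list(f)
#' @export
read_temporal_edge_list <- function(path, directed = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")

  n_fields <- lengths(fields)
  if (any(n_fields < 3L)) {
    bad <- lineno[which(n_fields < 3L)[1L]]
    stop(sprintf("parse error at line %d: expected at least 3 fields", bad))
  }
  source <- vapply(fields, `[[`, "", 1L)
  dest <- vapply(fields, `[[`, "", 2L)
  ts_raw <- vapply(fields, `[[`, "", 3L)
  timestamp <- suppressWarnings(as.numeric(ts_raw))
  if (any(!is.finite(timestamp))) {
    bad <- lineno[which(!is.finite(timestamp))[1L]]
    stop(sprintf("parse error at line %d: non-numeric timestamp", bad))
  }
  if (length(source) == 0L) stop("no edges")

  loops <- source == dest
  if (any(loops)) {
    warning(sprintf("skipped %d self-loop line(s)", sum(loops)))
    source <- source[!loops]
    dest <- dest[!loops]
    timestamp <- timestamp[!loops]
  }
  dup <- duplicated(edge_triple_key(source, dest, timestamp, directed))
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate edge triple(s)", sum(dup)))
    source <- source[!dup]
    dest <- dest[!dup]
    timestamp <- timestamp[!dup]
  }
  if (length(source) == 0L) stop("no edges")
  temporal_graph(source, dest, timestamp, directed = directed)
}

#' Write a temporal graph as an edge list
#'
#' Writes one `source dest timestamp` line per edge, in edge-id order, in the
#' format accepted by [read_temporal_edge_list()].
#'
#' @param g a [temporal_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_temporal_edge_list <- function(g, path) {
  stopifnot(inherits(g, "temporal_graph"))
  ts <- format(g$edges$timestamp, scientific = FALSE, trim = TRUE,
               drop0trailing = TRUE)
  writeLines(paste(g$edges$source, g$edges$dest, ts), path)
  invisible(path)
}

#' Edges incident to a node
#'
#' @param g a [temporal_graph()].
#' @param v a node identifier present in `g`.
#' @return The rows of `g$edges` having `v` as source or destination, in
#'   ascending `edge_id` order. Zero rows for an isolated node.
#' @export
incident_edges <- function(g, v) {
  stopifnot(inherits(g, "temporal_graph"))
  v <- as.character(v)
  if (length(v) != 1L || !v %in% g$nodes) stop("unknown node: ", v)
  ids <- g$incidence[[v]]
  g$edges[match(ids, g$edges$edge_id), , drop = FALSE]
}

#' Timestamp resolution of a temporal graph
#'
#' The resolution is the minimum positive difference between consecutive
#' distinct timestamps. Observation windows are conveniently expressed as
#' multiples of it (see the `delta_mult` option of [run_count()]).
#'
#' @param g a [temporal_graph()].
#' @return A single positive number.
#' @export
resolution <- function(g) {
  stopifnot(inherits(g, "temporal_graph"))
  ts <- sort(unique(g$edges$timestamp))
  if (length(ts) < 2L) {
    stop("resolution is undefined: fewer than two distinct timestamps")
  }
  min(diff(ts))
}

#' @export
print.temporal_graph <- function(x, ...) {
  cat(sprintf(
    "temporal_graph: %d nodes, %d edges (%s), timestamps [%s, %s]\n",
    length(x$nodes), nrow(x$edges),
    if (x$directed) "directed" else "undirected",
    format(min(x$edges$timestamp)), format(max(x$edges$timestamp))
  ))
  invisible(x)
}
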
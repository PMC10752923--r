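#' Dependence graphs
#'
#' A `dependence_graph` is the ground truth for a simulated dependence
#' network: an undirected, connected graph whose nodes index the channels of
#' the multivariate series and whose hop-count metric drives the mixing
#' weights.  Nodes are numbered `1..n_nodes`; edges are stored as a two-column
#' matrix of node pairs with `edges[, 1] < edges[, 2]`, no self-loops and no
#' duplicates.
#'
#' @param n_nodes number of nodes.
#' @param edges two-column matrix (or data.frame) of node index pairs.
#' @param labels optional character vector of node labels.
#' @return an object of class `dependence_graph`.
#' @export
dependence_graph <- function(n_nodes, edges, labels = NULL) {
  n_nodes <- check_count(n_nodes, 1, "n_nodes")
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(integer(), ncol = 2L)
  if (ncol(edges) != 2L) stop_invalid("`edges` must have two columns")
  storage.mode(edges) <- "integer"
  if (any(is.na(edges)) || any(edges < 1L) || any(edges > n_nodes))
    stop_invalid("edge endpoints must be node indices in 1..%d", n_nodes)
  if (any(edges[, 1] == edges[, 2]))
    stop_invalid("self-loops are not allowed")
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- unique(edges)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  dimnames(edges) <- NULL
  if (!is.null(labels) && length(labels) != n_nodes)
    stop_invalid("`labels` must have one entry per node")
  structure(list(n_nodes = n_nodes, edges = edges, labels = labels),
            class = "dependence_graph")
}

#' @export
print.dependence_graph <- function(x, ...) {
  cat(sprintf("dependence_graph: %d nodes, %d edges\n",
              x$n_nodes, nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    as.data.frame(g$edges),
    directed = FALSE,
    vertices = data.frame(name = seq_len(g$n_nodes)))
}

graph_is_connected <- function(g) {
  igraph::is_connected(as_igraph(g))
}

#' Circular ladder graph
#'
#' Two concentric cycles of `n_rungs` nodes joined by rungs: inner cycle
#' `1..n_rungs` (consecutive nodes adjacent, wrapped), outer cycle
#' `n_rungs+1..2*n_rungs`, rung edges `i -- i + n_rungs`.  The graph is
#' 3-regular with one essential cycle at the homotopy level; it is the
#' canonical "one main cycle" dependence pattern.
#'
#' @param n_rungs number of rungs (>= 3).
#' @return a [dependence_graph()] with `2 * n_rungs` nodes.
#' @export
circular_ladder <- function(n_rungs) {
  n_rungs <- check_count(n_rungs, 3, "n_rungs")
  i <- seq_len(n_rungs)
  nxt <- c(i[-1], 1L)
  edges <- rbind(cbind(i, nxt),                        # inner cycle
                 cbind(i + n_rungs, nxt + n_rungs),    # outer cycle
                 cbind(i, i + n_rungs))                # rungs
  dependence_graph(2L * n_rungs, edges)
}

#' Double circular ladder graph
#'
#' Two circular ladders ("lobes") of `n_rungs_per_lobe` rungs each, joined by
#' `n_bridges` pairs of rung-aligned bridge edges (each pair connects an
#' inner node of one lobe to an inner node of the other, and likewise for the
#' corresponding outer nodes).  The dependence network has exactly two main
#' cycles; bridges add only short secondary cycles.
#'
#' @param n_rungs_per_lobe rungs per lobe (>= 3).
#' @param n_bridges number of rung-aligned bridge pairs (default 1).
#' @return a [dependence_graph()] with `4 * n_rungs_per_lobe` nodes.
#' @export
double_circular_ladder <- function(n_rungs_per_lobe, n_bridges = 1) {
  n <- check_count(n_rungs_per_lobe, 3, "n_rungs_per_lobe")
  n_bridges <- check_count(n_bridges, 1, "n_bridges")
  if (n_bridges > n) stop_invalid("`n_bridges` cannot exceed the rung count")
  lobe <- circular_ladder(n)
  off <- 2L * n
  edges <- rbind(lobe$edges, lobe$edges + off)
  # bridge pair b joins rung b of lobe 1 to rung b of lobe 2
  for (b in seq_len(n_bridges)) {
    edges <- rbind(edges,
                   c(b, b + off),            # inner -- inner
                   c(b + n, b + n + off))    # outer -- outer
  }
  dependence_graph(4L * n, edges)
}

#' Torus grid graph
#'
#' `rows x cols` nodes on a 4-neighbour lattice with both axes periodic (a
#' rectangle with opposite edges identified), i.e. the graph Cartesian
#' product of two cycles.  Node `(r, c)` has index `(r - 1) * cols + c`.
#'
#' @param rows,cols grid dimensions (each >= 3).
#' @return a [dependence_graph()] with `rows * cols` nodes, all of degree 4.
#' @export
torus_grid <- function(rows, cols) {
  rows <- check_count(rows, 3, "rows")
  cols <- check_count(cols, 3, "cols")
  id <- function(r, c) (r - 1L) * cols + c
  r <- rep(seq_len(rows), each = cols)
  c <- rep(seq_len(cols), times = rows)
  right <- cbind(id(r, c), id(r, c %% cols + 1L))
  down <- cbind(id(r, c), id(r %% rows + 1L, c))
  dependence_graph(rows * cols, rbind(right, down))
}

#' Dodecahedral graph
#'
#' The 1-skeleton of the regular dodecahedron: 20 nodes, 30 edges, 3-regular,
#' girth 5.  Used as the spherical dependence pattern (its surface is a
#' 2-sphere, so the persistence pipeline should see one 2-dimensional
#' cavity).
#'
#' @return a [dependence_graph()] with 20 nodes and 30 edges.
#' @export
dodecahedron <- function() {
  ig <- igraph::make_graph("Dodecahedral")
  dependence_graph(igraph::vcount(ig), igraph::as_edgelist(ig, names = FALSE))
}

#' All-pairs hop-count distances
#'
#' Breadth-first-search shortest-path lengths between every pair of nodes.
#' The result is symmetric with a zero diagonal, satisfies the triangle
#' inequality, and `d[p, q] == 1` exactly when `(p, q)` is an edge.
#' Unreachable pairs (impossible for the built-in constructors, which are
#' connected) are reported as `Inf`.
#'
#' @param g a [dependence_graph()].
#' @return a `n_nodes x n_nodes` numeric matrix of hop counts.
#' @export
shortest_path_distances <- function(g) {
  stopifnot(inherits(g, "dependence_graph"))
  d <- igraph::distances(as_igraph(g))
  dimnames(d) <- NULL
  d
}

# edge-list text I/O ----------------------------------------------------

#' Read / write edge-list files
#'
#' Plain-text edge lists: one `i j` pair per line, 1-based node indices,
#' `#` starts a comment.  The writer records the node count in a header
#' comment so isolated trailing nodes survive a round trip.
#'
#' @param path file path.
#' @param g a [dependence_graph()].
#' @param n_nodes optional node count override for the reader (defaults to
#'   the header comment if present, otherwise the largest index seen).
#' @return the reader returns a [dependence_graph()]; the writer returns
#'   `path` invisibly.
#' @export
read_edge_list <- function(path, n_nodes = NULL) {
  lines <- readLines(path)
  header <- grep("^#\\s*n_nodes:", lines, value = TRUE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_invalid("no edges found in '%s'", path)
  parts <- strsplit(lines, "\\s+")
  if (any(lengths(parts) != 2L))
    stop_invalid("each edge line must contain exactly two node indices")
  edges <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  if (is.null(n_nodes)) {
    n_nodes <- if (length(header))
      as.integer(sub("^#\\s*n_nodes:\\s*", "", header[1])) else max(edges)
  }
  dependence_graph(n_nodes, edges)
}

#' @rdname read_edge_list
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "dependence_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_nodes: %d", g$n_nodes), con)
  writeLines(sprintf("%d %d", g$edges[, 1], g$edges[, 2]), con)
  invisible(path)
}
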
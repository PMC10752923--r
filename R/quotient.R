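#' Polygon-quotient specification
#'
#' Describes a flat rectangle (the fundamental domain, taken as the unit
#' square) with opposite edges optionally identified, encoding a surface as a
#' quotient of a polygon: both axes wrapped gives a torus, one axis a
#' cylinder, and an orientation-reversing identification gives a Moebius band
#' or Klein bottle.  `rows`/`cols` give the regular-grid resolution along the
#' y and x axes respectively.
#'
#' @param rows,cols grid resolution used by the `regular` sampling mode
#'   (each >= 3 when the corresponding axis wraps).
#' @param wrap_rows,wrap_cols identify the bottom/top (resp. left/right)
#'   edges of the rectangle.
#' @param reverse_rows,reverse_cols make the corresponding identification
#'   orientation-reversing.
#' @return an object of class `polygon_quotient_spec`.
#' @export
polygon_quotient_spec <- function(rows, cols, wrap_rows = TRUE,
                                  wrap_cols = TRUE, reverse_rows = FALSE,
                                  reverse_cols = FALSE) {
  min_rows <- if (isTRUE(wrap_rows)) 3 else 1
  min_cols <- if (isTRUE(wrap_cols)) 3 else 1
  rows <- check_count(rows, min_rows, "rows")
  cols <- check_count(cols, min_cols, "cols")
  if (isTRUE(reverse_rows) && !isTRUE(wrap_rows))
    stop_invalid("`reverse_rows` requires `wrap_rows`")
  if (isTRUE(reverse_cols) && !isTRUE(wrap_cols))
    stop_invalid("`reverse_cols` requires `wrap_cols`")
  structure(list(rows = rows, cols = cols,
                 wrap_rows = isTRUE(wrap_rows), wrap_cols = isTRUE(wrap_cols),
                 reverse_rows = isTRUE(reverse_rows),
                 reverse_cols = isTRUE(reverse_cols)),
            class = "polygon_quotient_spec")
}

# Deck transformations for the 3x3 tiling: the copy at offset (dx, dy) is
# the image of the fundamental domain under the corresponding identification
# map.  For a plain wrap this is a translation; for an orientation-reversing
# wrap the transverse coordinate is flipped on odd offsets.
tile_points <- function(x, y, spec, dx, dy) {
  if (dx != 0 && spec$reverse_cols && (dx %% 2 != 0)) y <- 1 - y
  if (dy != 0 && spec$reverse_rows && (dy %% 2 != 0)) x <- 1 - x
  cbind(x + dx, y + dy)
}

#' Sample a dependence graph from a polygon quotient
#'
#' Places points in the flat fundamental rectangle (a regular grid or a
#' uniform random sample), then builds the neighbourhood graph of the
#' quotient surface: the fundamental domain is tiled 3x3 by its deck
#' transformations, a Voronoi/Delaunay tessellation is computed on the tiled
#' point set, and two nodes are adjacent when their Voronoi cells share a
#' border (corner-only contacts do not count, so a regular grid yields rook
#' adjacency).  Adjacency read off the central copy therefore respects the
#' edge identifications.
#'
#' With `mode = "regular"` and both axes wrapped the result is identical to
#' [torus_grid()] with the same dimensions, node for node.
#'
#' @param spec a [polygon_quotient_spec()].
#' @param n_points number of points for `mode = "uniform_random"` (>= 4);
#'   ignored in `regular` mode, which uses `spec$rows * spec$cols` points.
#' @param seed integer seed for the random sample.
#' @param mode `"regular"` or `"uniform_random"`.
#' @param max_retries resample attempts (seed incremented each time) when the
#'   tessellation degenerates or the sampled graph is disconnected.
#' @return a [dependence_graph()].
#' @export
sample_quotient_graph <- function(spec, n_points = NULL, seed = 1,
                                  mode = c("regular", "uniform_random"),
                                  max_retries = 10) {
  stopifnot(inherits(spec, "polygon_quotient_spec"))
  mode <- match.arg(mode)
  seed <- check_count(seed, 0, "seed")
  if (mode == "regular") {
    # cell centres, aligned with torus_grid node ids: (r - 1) * cols + c
    r <- rep(seq_len(spec$rows), each = spec$cols)
    c <- rep(seq_len(spec$cols), times = spec$rows)
    pts <- cbind((c - 0.5) / spec$cols, (r - 0.5) / spec$rows)
    return(quotient_adjacency(pts, spec))
  }
  n_points <- check_count(n_points, 4, "n_points")
  for (attempt in seq_len(max_retries)) {
    set.seed(seed + attempt - 1L)
    pts <- cbind(runif(n_points), runif(n_points))
    g <- tryCatch(quotient_adjacency(pts, spec), error = function(e) NULL)
    if (!is.null(g) && graph_is_connected(g)) return(g)
  }
  stop_invalid(paste("no connected tessellation after %d attempts;",
                     "increase `n_points` or `max_retries`"), max_retries)
}

quotient_adjacency <- function(pts, spec) {
  n <- nrow(pts)
  dxs <- if (spec$wrap_cols) -1:1 else 0
  dys <- if (spec$wrap_rows) -1:1 else 0
  tiles <- expand.grid(dx = dxs, dy = dys)
  # central copy first so node ids 1..n refer to the fundamental domain
  tiles <- tiles[order(tiles$dx != 0 | tiles$dy != 0), , drop = FALSE]
  all_pts <- do.call(rbind, lapply(seq_len(nrow(tiles)), function(i) {
    tile_points(pts[, 1], pts[, 2], spec, tiles$dx[i], tiles$dy[i])
  }))
  owner <- rep.int(seq_len(n), nrow(tiles))
  # drop exact duplicates deldir would reject (cannot occur for generic
  # samples; guards hand-crafted point sets on the boundary)
  keep <- !duplicated(round(all_pts, 12))
  all_pts <- all_pts[keep, , drop = FALSE]
  owner <- owner[keep]
  dd <- deldir::deldir(all_pts[, 1], all_pts[, 2],
                       rw = c(min(dxs) - 0.5, max(dxs) + 1.5,
                              min(dys) - 0.5, max(dys) + 1.5))
  seg <- dd$dirsgs
  # Voronoi border segments with positive length = genuine shared borders
  len <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
  seg <- seg[len > 1e-9, , drop = FALSE]
  a <- owner[seg$ind1]
  b <- owner[seg$ind2]
  # keep contacts involving at least one point of the central copy
  central <- seg$ind1 <= n | seg$ind2 <= n
  edges <- cbind(a, b)[central & a != b, , drop = FALSE]
  if (nrow(edges) == 0L) stop_invalid("tessellation produced no edges")
  dependence_graph(n, edges)
}
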
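#' Vietoris-Rips persistent homology
#'
#' Computes the persistence diagram of the Vietoris-Rips filtration of a
#' finite metric space given by a distance matrix: a simplex enters the
#' filtration at the largest pairwise distance among its vertices, and
#' homology classes (connected components, cycles, cavities) are tracked as
#' the threshold grows.  Coefficients are in the field Z/2.
#'
#' The computation uses the package's persistent-cohomology engine (implicit
#' coboundaries, clearing, emergent-pair shortcut), which handles the 153
#' node torus pipeline up to dimension 2 in seconds.  By default the
#' filtration is truncated at the enclosing radius
#' `min_p max_q D[p, q]`, beyond which the complex is a cone and no feature
#' of any dimension can be born or die; the diagram is identical to the full
#' filtration's apart from the one essential dimension-0 class, reported
#' with death `Inf`.
#'
#' @param D symmetric distance matrix with zero diagonal (e.g. a
#'   [coherence_distance()]).
#' @param max_dim largest homology dimension to compute (1, 2 or 3).
#' @param threshold filtration cutoff; `NULL` (default) uses the enclosing
#'   radius, `Inf` the full filtration.
#' @return a `persistence_diagram`: data.frame with columns `dimension`,
#'   `birth`, `death` (`Inf` marks essential classes), the threshold kept as
#'   attribute `"threshold"`.  Zero-length features are omitted.
#' @examples
#' # four points on a square: one 1-cycle born at the side length,
#' # dying at the diagonal
#' D <- matrix(1.5, 4, 4) - diag(1.5, 4)
#' D[1, 2] <- D[2, 3] <- D[3, 4] <- D[1, 4] <- 1
#' D[lower.tri(D)] <- t(D)[lower.tri(D)]
#' vr_persistence(D, max_dim = 1)
#' @export
vr_persistence <- function(D, max_dim = 1, threshold = NULL) {
  D <- unclass(as.matrix(D))
  if (nrow(D) != ncol(D)) stop_invalid("`D` must be square")
  if (any(!is.finite(D)) || any(D < 0))
    stop_invalid("`D` must be finite and non-negative")
  if (any(abs(D - t(D)) > 1e-12)) stop_invalid("`D` must be symmetric")
  if (any(diag(D) != 0)) stop_invalid("`D` must have a zero diagonal")
  max_dim <- check_count(max_dim, 0, "max_dim")
  if (max_dim > 3) stop_invalid("`max_dim` must be at most 3")
  if (is.null(threshold)) {
    threshold <- if (nrow(D) > 1) min(apply(D, 1, max)) else 0
  }
  threshold <- check_number(threshold, "threshold", lower = 0)
  if (!is.finite(threshold)) threshold <- max(D) # full filtration
  pd <- .rips_persistence_cpp(D, as.integer(max_dim), threshold)
  pd <- pd[order(pd$dimension, pd$birth, pd$death), , drop = FALSE]
  rownames(pd) <- NULL
  structure(pd, threshold = threshold,
            class = c("persistence_diagram", "data.frame"))
}

new_persistence_diagram <- function(dimension, birth, death,
                                    threshold = NA_real_) {
  structure(data.frame(dimension = as.integer(dimension),
                       birth = as.numeric(birth), death = as.numeric(death)),
            threshold = threshold,
            class = c("persistence_diagram", "data.frame"))
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("persistence_diagram: %d features\n", nrow(x)))
  for (k in sort(unique(x$dimension)))
    cat(sprintf("  dim %d: %d features (%d essential)\n", k,
                sum(x$dimension == k),
                sum(x$dimension == k & is.infinite(x$death))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Total persistence
#'
#' The per-dimension topological summary `P_k = sum_i (death_i - birth_i)`
#' over the dimension-`k` features of a diagram.  Features with infinite
#' death (essential classes, e.g. the last connected component) are excluded
#' by default; `infinite = "truncate"` instead truncates their death at the
#' filtration threshold.
#'
#' @param pd a `persistence_diagram`.
#' @param dim homology dimension `k`.
#' @param infinite how to treat essential classes.
#' @return the non-negative scalar `P_k` (0 for an empty dimension).
#' @export
total_persistence <- function(pd, dim, infinite = c("exclude", "truncate")) {
  infinite <- match.arg(infinite)
  rows <- pd[pd$dimension == dim, , drop = FALSE]
  death <- rows$death
  if (infinite == "truncate") {
    cap <- attr(pd, "threshold")
    if (is.null(cap) || is.na(cap))
      cap <- max(0, death[is.finite(death)], rows$birth)
    death <- pmin(death, cap)
  } else {
    keep <- is.finite(death)
    rows <- rows[keep, , drop = FALSE]
    death <- death[keep]
  }
  if (nrow(rows) == 0) return(0)
  sum(death - rows$birth)
}

#' Count prominent features (empirical Betti numbers)
#'
#' The number of dimension-`k` features whose lifetime is at least
#' `rel_threshold` times the largest dimension-`k` lifetime.  Long-lived
#' features far from the diagonal represent the main topological structure;
#' short-lived ones are sampling noise.  Essential (infinite-death) features
#' are always counted as prominent.
#'
#' @param pd a `persistence_diagram`.
#' @param dim homology dimension `k`.
#' @param rel_threshold relative lifetime cutoff in `(0, 1]` (default 0.5).
#' @return a non-negative integer count (0 for an empty dimension).
#' @export
prominent_features <- function(pd, dim, rel_threshold = 0.5) {
  rel_threshold <- check_number(rel_threshold, "rel_threshold",
                                lower = 0, upper = 1, strict_lower = TRUE)
  rows <- pd[pd$dimension == dim, , drop = FALSE]
  if (nrow(rows) == 0) return(0L)
  essential <- is.infinite(rows$death)
  life <- rows$death[!essential] - rows$birth[!essential]
  count <- sum(essential)
  if (length(life))
    count <- count + sum(life >= rel_threshold * max(life))
  as.integer(count)
}

# diagram text I/O ------------------------------------------------------

#' Read / write persistence diagrams as delimited text
#'
#' Three tab-separated columns `dimension`, `birth`, `death`, with the token
#' `inf` marking essential classes.
#'
#' @param pd a `persistence_diagram`.
#' @param path file path.
#' @return the reader returns a `persistence_diagram`; the writer returns
#'   `path` invisibly.
#' @export
write_persistence_diagram <- function(pd, path) {
  out <- data.frame(dimension = pd$dimension,
                    birth = format(pd$birth, digits = 12, trim = TRUE),
                    death = ifelse(is.infinite(pd$death), "inf",
                                   format(pd$death, digits = 12,
                                          trim = TRUE)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_persistence_diagram
#' @export
read_persistence_diagram <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("integer", "numeric", "character"))
  death <- ifelse(tolower(x$death) == "inf", Inf, as.numeric(x$death))
  new_persistence_diagram(x$dimension, x$birth, death)
}

#' Full coherence-persistence pipeline
#'
#' Convenience wrapper running the analysis half end to end: periodogram,
#' Daniell smoothing, band coherence, coherence distance, Vietoris-Rips
#' persistence.
#'
#' @param y a [multivariate_series()].
#' @param band_hz frequency band in Hz (default the 8-12 Hz mid band).
#' @param half_width smoothing half-width in bins (default
#'   `ceiling(sqrt(T) / 2)`).
#' @param transform distance transform, see [coherence_distance()].
#' @param max_dim largest homology dimension (default 2).
#' @return a `persistence_diagram`; the distance matrix is attached as
#'   attribute `"distance"`.
#' @export
coherence_persistence <- function(y, band_hz = c(8, 12), half_width = NULL,
                                  transform = "one_minus", max_dim = 2) {
  est <- smooth_periodogram(periodogram(y), half_width = half_width)
  D <- coherence_distance(band_coherence(est, band_hz), transform = transform)
  pd <- vr_persistence(D, max_dim = max_dim)
  attr(pd, "distance") <- D
  pd
}
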
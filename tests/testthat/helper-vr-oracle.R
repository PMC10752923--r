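# Brute-force Vietoris-Rips persistence by explicit boundary-matrix
# reduction over Z/2.  Independent of the package's cohomology engine; only
# usable for small point sets (it enumerates every simplex up to
# max_dim + 1).  Returns bars like vr_persistence(): data.frame(dimension,
# birth, death), zero-length bars dropped, essentials with death = Inf.
vr_persistence_bruteforce <- function(D, max_dim = 1) {
  n <- nrow(D)
  simplices <- list()
  for (k in 0:(max_dim + 1)) {
    combs <- utils::combn(n, k + 1)
    for (j in seq_len(ncol(combs))) {
      v <- combs[, j]
      diam <- if (k == 0) 0 else max(D[v, v])
      simplices[[length(simplices) + 1L]] <- list(v = v, dim = k, diam = diam)
    }
  }
  # filtration order: diameter, then dimension (faces precede cofaces)
  ord <- order(vapply(simplices, `[[`, 0, "diam"),
               vapply(simplices, `[[`, 0, "dim"))
  simplices <- simplices[ord]
  m <- length(simplices)
  key <- vapply(simplices, function(s) paste(sort(s$v), collapse = "-"), "")
  pos <- seq_len(m)
  names(pos) <- key

  columns <- vector("list", m)
  for (j in seq_len(m)) {
    s <- simplices[[j]]
    if (s$dim == 0) {
      columns[[j]] <- integer()
    } else {
      faces <- vapply(seq_along(s$v), function(i)
        pos[[paste(sort(s$v[-i]), collapse = "-")]], 0L)
      columns[[j]] <- sort(faces)
    }
  }

  low_of <- rep(NA_integer_, m)   # pivot row -> column holding it
  pair <- rep(NA_integer_, m)
  for (j in seq_len(m)) {
    col <- columns[[j]]
    while (length(col) > 0) {
      low <- max(col)
      other <- low_of[low]
      if (is.na(other)) break
      # Z/2 addition = symmetric difference
      col <- sort(union(setdiff(col, columns[[other]]),
                        setdiff(columns[[other]], col)))
    }
    columns[[j]] <- col
    if (length(col) > 0) {
      low <- max(col)
      low_of[low] <- j
      pair[low] <- j
    }
  }

  bars <- data.frame(dimension = integer(), birth = numeric(),
                     death = numeric())
  for (i in seq_len(m)) {
    if (length(columns[[i]]) > 0) next        # negative simplex: kills
    s <- simplices[[i]]
    death <- if (is.na(pair[i])) Inf else simplices[[pair[i]]]$diam
    if (s$dim > max_dim) next
    if (is.finite(death) && death <= s$diam) next
    bars <- rbind(bars, data.frame(dimension = s$dim, birth = s$diam,
                                   death = death))
  }
  bars <- bars[order(bars$dimension, bars$birth, bars$death), ]
  rownames(bars) <- NULL
  bars
}

# canonical multiset comparison of two bar sets
sorted_bars <- function(pd, dim) {
  rows <- pd[pd$dimension == dim, , drop = FALSE]
  rows <- rows[order(rows$birth, rows$death), , drop = FALSE]
  cbind(rows$birth, rows$death)
}

random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  x <- matrix(runif(n * 3), n, 3)
  as.matrix(dist(x))
}
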
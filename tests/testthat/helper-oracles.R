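# Independent breadth-first-search all-pairs hop counts, written directly on
# the edge list (no graph library) to cross-check shortest_path_distances().
bfs_distances <- function(g) {
  n <- g$n_nodes
  adj <- vector("list", n)
  for (r in seq_len(nrow(g$edges))) {
    i <- g$edges[r, 1]; j <- g$edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.infinite(d[s, nxt])]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

node_degrees <- function(g) tabulate(g$edges, g$n_nodes)

# shortest cycle length by BFS from each edge with that edge removed
graph_girth <- function(g) {
  best <- Inf
  for (r in seq_len(nrow(g$edges))) {
    h <- g
    h$edges <- g$edges[-r, , drop = FALSE]
    d <- bfs_distances(h)
    best <- min(best, d[g$edges[r, 1], g$edges[r, 2]] + 1)
  }
  best
}
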
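test_that("circular ladder has the documented size, regularity and labeling", {
  g <- circular_ladder(15)
  expect_equal(g$n_nodes, 30)
  expect_equal(nrow(g$edges), 45)
  expect_true(all(node_degrees(g) == 3))
  d <- shortest_path_distances(g)
  # inner-cycle-consecutive labeling: nodes 1 and 6 are five hops apart,
  # so at K = 2 they share no latent process
  expect_equal(d[1, 2], 1)
  expect_equal(d[1, 6], 5)
  expect_error(circular_ladder(2), "n_rungs")
})

test_that("circular ladder is vertex-transitive in its distance profile", {
  d <- shortest_path_distances(circular_ladder(15))
  profiles <- apply(d, 1, function(r) paste(sort(r), collapse = ","))
  expect_length(unique(profiles), 1)
})

test_that("double circular ladder joins two lobes into a connected graph", {
  g <- double_circular_ladder(8)
  expect_equal(g$n_nodes, 32)
  expect_false(anyNA(match(seq_len(g$n_nodes), g$edges)))
  d <- bfs_distances(g)
  expect_true(all(is.finite(d)))
  # bridges add two degree-4 nodes per lobe; the rest stay 3-regular
  expect_equal(sort(unique(node_degrees(g))), c(3, 4))
  expect_equal(sum(node_degrees(g) == 4), 4)
})

test_that("torus grid is the 4-regular periodic lattice with L1 hop metric", {
  g <- torus_grid(9, 17)
  expect_equal(g$n_nodes, 153)
  expect_true(all(node_degrees(g) == 4))
  d <- shortest_path_distances(g)
  expect_equal(max(d), floor(9 / 2) + floor(17 / 2))
  expect_equal(d, t(d))
  expect_error(torus_grid(2, 5), "rows")
})

test_that("dodecahedron has 20 nodes, 30 edges, girth 5, diameter 5", {
  g <- dodecahedron()
  expect_equal(g$n_nodes, 20)
  expect_equal(nrow(g$edges), 30)
  expect_true(all(node_degrees(g) == 3))
  expect_equal(graph_girth(g), 5)
  expect_equal(max(bfs_distances(g)), 5)
})

test_that("hop distances agree with an independent BFS and are metric", {
  for (g in list(circular_ladder(5), double_circular_ladder(4),
                 torus_grid(3, 5), dodecahedron())) {
    d <- shortest_path_distances(g)
    expect_equal(d, bfs_distances(g))
    expect_true(all(diag(d) == 0))
    expect_equal(d, t(d))
    # edge characterization and exhaustive triangle inequality
    edge_set <- d == 1
    expect_equal(sum(edge_set) / 2, nrow(g$edges))
    n <- g$n_nodes
    for (k in seq_len(n))
      expect_true(all(d <= outer(d[, k], d[k, ], `+`) + 1e-9))
  }
})

test_that("constructors reject malformed inputs", {
  expect_error(dependence_graph(3, rbind(c(1, 1))), "self-loops")
  expect_error(dependence_graph(3, rbind(c(1, 4))), "node indices")
  g <- dependence_graph(3, rbind(c(1, 2), c(2, 1), c(1, 2)))
  expect_equal(nrow(g$edges), 1)  # duplicates and orientation collapsed
})

test_that("edge-list files round-trip", {
  g <- double_circular_ladder(5)
  path <- withr::local_tempfile(fileext = ".txt")
  write_edge_list(g, path)
  g2 <- read_edge_list(path)
  expect_equal(g2$n_nodes, g$n_nodes)
  expect_equal(g2$edges, g$edges)
})

test_that("regular quotient sampling with both wraps reproduces the torus", {
  gq <- sample_quotient_graph(polygon_quotient_spec(9, 17), mode = "regular")
  gt <- torus_grid(9, 17)
  expect_equal(gq$n_nodes, gt$n_nodes)
  expect_equal(gq$edges, gt$edges)
})

test_that("cylinder quotient has degree-3 boundary rows, degree-4 interior", {
  g <- sample_quotient_graph(
    polygon_quotient_spec(5, 8, wrap_rows = FALSE), mode = "regular")
  deg <- node_degrees(g)
  boundary <- c(1:8, 33:40)  # first and last grid rows
  expect_true(all(deg[boundary] == 3))
  expect_true(all(deg[-boundary] == 4))
})

test_that("uniform random torus samples are connected across seeds", {
  spec <- polygon_quotient_spec(3, 3)
  for (s in 1:3) {
    g <- sample_quotient_graph(spec, n_points = 120, seed = s,
                               mode = "uniform_random")
    expect_equal(g$n_nodes, 120)
    expect_true(all(is.finite(bfs_distances(g))))
  }
})
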
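square_distance <- function(side = 1, diagonal = 1.5) {
  D <- matrix(diagonal, 4, 4) - diag(diagonal, 4)
  D[1, 2] <- D[2, 3] <- D[3, 4] <- D[1, 4] <- side
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

test_that("the 4-point square yields the hand-computed diagram", {
  pd <- vr_persistence(square_distance(), max_dim = 1, threshold = Inf)
  d1 <- pd[pd$dimension == 1, ]
  expect_equal(nrow(d1), 1)
  expect_equal(d1$birth, 1)     # cycle closes when all sides are present
  expect_equal(d1$death, 1.5)   # diagonals fill the square
  d0 <- pd[pd$dimension == 0, ]
  expect_equal(sum(is.infinite(d0$death)), 1)
  expect_equal(sort(d0$death), c(1, 1, 1, Inf))
})

test_that("a single point has one essential component and nothing else", {
  pd <- vr_persistence(matrix(0, 1, 1), max_dim = 1)
  expect_equal(nrow(pd), 1)
  expect_equal(pd$dimension, 0L)
  expect_equal(pd$birth, 0)
  expect_true(is.infinite(pd$death))
})

test_that("engine agrees with brute-force boundary-matrix reduction", {
  for (s in 1:12) {
    D <- random_distance_matrix(6, seed = 100 + s)
    a <- vr_persistence(D, max_dim = 2, threshold = Inf)
    b <- vr_persistence_bruteforce(D, max_dim = 2)
    for (k in 0:2)
      expect_equal(sorted_bars(a, k), sorted_bars(b, k), tolerance = 1e-12)
  }
})

test_that("the enclosing-radius default reproduces the full filtration", {
  D <- random_distance_matrix(9, seed = 3)
  a <- vr_persistence(D, max_dim = 2)
  b <- vr_persistence(D, max_dim = 2, threshold = Inf)
  for (k in 0:2)
    expect_equal(sorted_bars(a, k), sorted_bars(b, k))
})

test_that("persistence is scale-equivariant", {
  D <- random_distance_matrix(7, seed = 5)
  a <- vr_persistence(D, max_dim = 1, threshold = Inf)
  b <- vr_persistence(3.5 * D, max_dim = 1, threshold = Inf)
  for (k in 0:1) {
    expect_equal(3.5 * sorted_bars(a, k), sorted_bars(b, k),
                 tolerance = 1e-12)
    expect_equal(total_persistence(b, k), 3.5 * total_persistence(a, k),
                 tolerance = 1e-12)
  }
})

test_that("strictly increasing transforms preserve feature counts", {
  D <- random_distance_matrix(7, seed = 6)
  a <- vr_persistence(D, max_dim = 1, threshold = Inf)
  b <- vr_persistence(sqrt(D), max_dim = 1, threshold = Inf)
  c <- vr_persistence(D^2, max_dim = 1, threshold = Inf)
  for (k in 0:1) {
    expect_equal(sum(b$dimension == k), sum(a$dimension == k))
    expect_equal(sum(c$dimension == k), sum(a$dimension == k))
  }
})

test_that("invalid distance matrices are rejected", {
  D <- random_distance_matrix(4, seed = 1)
  A <- D; A[1, 2] <- A[1, 2] + 1
  expect_error(vr_persistence(A), "symmetric")
  B <- D; diag(B) <- 0.1
  expect_error(vr_persistence(B), "diagonal")
  expect_error(vr_persistence(D - 1), "non-negative")
})

test_that("total persistence sums lifetimes and is additive", {
  pd <- topodep:::new_persistence_diagram(
    dimension = c(1L, 1L, 0L), birth = c(0.2, 0.1, 0),
    death = c(0.5, 0.9, Inf))
  expect_equal(total_persistence(pd, 1), 1.1)
  expect_equal(total_persistence(pd, 2), 0)
  expect_equal(total_persistence(pd, 0), 0)  # essential excluded
  attr(pd, "threshold") <- 2
  expect_equal(total_persistence(pd, 0, infinite = "truncate"), 2)
  # additivity over concatenation
  half <- topodep:::new_persistence_diagram(1L, 0.1, 0.9)
  other <- topodep:::new_persistence_diagram(1L, 0.2, 0.5)
  both <- topodep:::new_persistence_diagram(c(1L, 1L), c(0.1, 0.2),
                                            c(0.9, 0.5))
  expect_equal(total_persistence(both, 1),
               total_persistence(half, 1) + total_persistence(other, 1))
})

test_that("prominent features counts long-lived bars only", {
  pd <- topodep:::new_persistence_diagram(
    dimension = c(1L, 1L, 1L), birth = c(0, 0, 0),
    death = c(1, 0.6, 0.3))
  expect_equal(prominent_features(pd, 1, rel_threshold = 0.5), 2L)
  expect_equal(prominent_features(pd, 1, rel_threshold = 0.7), 1L)
  expect_equal(prominent_features(pd, 2), 0L)
  expect_error(prominent_features(pd, 1, rel_threshold = 0), "rel_threshold")
})

test_that("diagrams round-trip through the three-column text format", {
  pd <- vr_persistence(square_distance(), max_dim = 1, threshold = Inf)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_persistence_diagram(pd, path)
  pd2 <- read_persistence_diagram(path)
  expect_equal(pd2$dimension, pd$dimension)
  expect_equal(pd2$birth, pd$birth, tolerance = 1e-10)
  expect_equal(pd2$death, pd$death, tolerance = 1e-10)
})

test_that("hop-metric ladders satisfy the cycle-detection sizing rule", {
  # with K = 2 the cycle is detectable once the cycle diameter P/4 exceeds
  # 2K; probe the deterministic correlation-based distance matrix
  prominent_on_ladder <- function(n_rungs) {
    g <- circular_ladder(n_rungs)
    R <- theoretical_correlation(mixing_weights(
      shortest_path_distances(g), K = 2))
    pd <- vr_persistence(coherence_distance(R^2), max_dim = 1)
    pd1 <- pd[pd$dimension == 1, ]
    life <- pd1$death - pd1$birth
    # a dominant long bar: at least twice as long as any other
    length(life) > 0 && max(life) > 0.2 &&
      (length(life) == 1 || max(life) > 2 * sort(life, decreasing = TRUE)[2])
  }
  expect_true(prominent_on_ladder(15))   # P = 30 >= 16
  expect_true(prominent_on_ladder(8))    # P = 16, boundary case
  expect_false(prominent_on_ladder(3))   # P = 6, far below the bound
})
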
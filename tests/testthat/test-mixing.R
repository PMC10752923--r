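test_that("mixing weights follow the truncated decay rule", {
  d <- matrix(c(0, 1, 2, 3,
                1, 0, 1, 2,
                2, 1, 0, 1,
                3, 2, 1, 0), 4, 4)
  W <- mixing_weights(d, K = 2)
  expect_equal(W[1, 1], 1)
  expect_equal(W[1, 2], 1 / 2)
  expect_equal(W[1, 3], 1 / 3)
  expect_equal(W[1, 4], 0)          # beyond the cutoff
  expect_equal(mixing_weights(d, K = 0), diag(4))
  expect_equal(mixing_weights(d, K = 2, decay = "inv_quadratic")[1, 3],
               1 / 5)
  expect_equal(mixing_weights(d, K = 2, decay = "exponential")[1, 2],
               exp(-1))
  expect_error(mixing_weights(d, K = 2, decay = "linear"), "arg")
})

test_that("circular-ladder rows have the documented K = 2 support", {
  d <- shortest_path_distances(circular_ladder(15))
  W <- mixing_weights(d, K = 2)
  expect_true(all(rowSums(W > 0) == 8))  # self + 3 at d=1 + 4 at d=2
})

test_that("worked circular-ladder correlations are reproduced exactly", {
  g <- circular_ladder(15)
  W <- mixing_weights(shortest_path_distances(g), K = 2)
  R <- theoretical_correlation(W, noise_sd = 0)
  # shared-latent expansion for adjacent inner nodes: covariance 10/6,
  # channel variance 79/36, correlation 60/79 ~ 0.76
  expect_equal(R[1, 2], (10 / 6) / (79 / 36), tolerance = 1e-12)
  expect_equal(round(R[1, 2], 2), 0.76)
  expect_identical(R[1, 6], 0)            # no shared latents at d = 5
  expect_equal(R[1, 2], R[5, 6])          # vertex transitivity
})

test_that("theoretical correlation is a valid correlation matrix", {
  for (g in list(circular_ladder(8), dodecahedron())) {
    W <- mixing_weights(shortest_path_distances(g), K = 2)
    R <- theoretical_correlation(W, noise_sd = 0.5)
    expect_equal(diag(R), rep(1, nrow(R)))
    expect_equal(R, t(R))
    expect_true(min(eigen(R, symmetric = TRUE,
                          only.values = TRUE)$values) > -1e-10)
  }
})

test_that("correlation decays with hop distance and vanishes beyond 2K", {
  for (K in 1:2) {
    g <- circular_ladder(15)
    d <- shortest_path_distances(g)
    R <- theoretical_correlation(mixing_weights(d, K = K))
    off <- upper.tri(d)
    mean_at <- vapply(1:(2 * K), function(h)
      mean(R[off][d[off] == h]), 0)
    expect_true(all(diff(mean_at) < 0))
    expect_true(all(R[off][d[off] > 2 * K] == 0))
  }
})

test_that("simulated series matches the theoretical correlation", {
  g <- circular_ladder(8)
  y <- simulate_network_series(g, band_preset("alpha"), K = 2,
                               n_time = 20000, noise_sd = 0, seed = 2)
  expect_equal(dim(y$y), c(20000, 16))
  R_hat <- cor(y$y)
  R <- theoretical_correlation(mixing_weights(
    shortest_path_distances(g), K = 2))
  err <- abs(R_hat - R)[upper.tri(R)]
  # band-limited latents decorrelate slowly (integral time scale ~ 20
  # samples at M = 1.05), inflating entrywise sampling error ~ 4x over the
  # iid rate; the average agreement is the stable convergence check
  expect_lt(mean(err), 0.03)
  expect_lt(max(err), 0.1)
})

test_that("K = 0 and zero noise reduce the series to the latent panel", {
  g <- circular_ladder(4)
  y <- simulate_network_series(g, band_preset("alpha"), K = 0,
                               n_time = 500, noise_sd = 0, seed = 9)
  z <- simulate_ar2_panel(band_preset("alpha"), g$n_nodes, 500, seed = 9)
  expect_equal(y$y, unclass(z), ignore_attr = TRUE)
})

test_that("noise level for a target SNR uses channel-averaged power", {
  expect_equal(noise_sd_for_snr(diag(3), 1), 1)
  W <- mixing_weights(shortest_path_distances(dodecahedron()), K = 2)
  expect_equal(noise_sd_for_snr(W, 4), sqrt(mean(diag(tcrossprod(W))) / 4))
  expect_lt(noise_sd_for_snr(W, 1e8), 1e-3)
  expect_error(noise_sd_for_snr(W, 0), "target_snr")
})

test_that("series files round-trip with their sampling rate", {
  y <- simulate_network_series(circular_ladder(3), band_preset("theta"),
                               n_time = 50, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_series(y, path)
  y2 <- read_series(path)
  expect_equal(y2$sampling_rate_hz, 100)
  expect_equal(y2$y, y$y, tolerance = 1e-8, ignore_attr = TRUE)
})
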
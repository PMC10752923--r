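white_noise_series <- function(n_time, n_chan, seed, sr = 100) {
  set.seed(seed)
  multivariate_series(matrix(rnorm(n_time * n_chan), n_time, n_chan), sr)
}

test_that("periodogram satisfies Parseval and the pure-cosine identity", {
  y <- white_noise_series(256, 3, seed = 1)
  est <- periodogram(y)
  centered <- sweep(y$y, 2, colMeans(y$y))
  power <- spectral_density(est)
  expect_equal(colSums(power) / nrow(y$y), colMeans(centered^2),
               tolerance = 1e-8)
  # a cosine at an exact Fourier frequency puts all mass in two mirrored bins
  t <- 1:256
  yc <- multivariate_series(cbind(cos(2 * pi * 16 * t / 256), rnorm(256)),
                            100)
  pc <- spectral_density(periodogram(yc))[, 1]
  expect_equal(sum(pc[c(17, 256 - 15)]), sum(pc), tolerance = 1e-9)
})

test_that("raw periodogram matrices are rank-1 Hermitian PSD", {
  y <- white_noise_series(64, 4, seed = 2)
  est <- periodogram(y)
  for (bin in c(2, 9, 30)) {
    I_k <- spectral_matrix(est, bin = bin)
    expect_equal(I_k, Conj(t(I_k)), tolerance = 1e-12)
    ev <- eigen(I_k, only.values = TRUE)$values
    expect_true(all(Re(ev) > -1e-10))
    expect_lt(sum(Mod(ev) > 1e-10 * max(Mod(ev))), 2)  # rank 1
  }
})

test_that("white-noise periodogram diagonal is flat on average", {
  power <- 0
  for (s in 1:20)
    power <- power + spectral_density(periodogram(
      white_noise_series(128, 2, seed = s)))[, 1]
  power <- power / 20
  # chi-square spread of the mean of 20 exponentials
  expect_lt(max(abs(power[2:64] / mean(power[2:64]) - 1)), 1)
})

test_that("smoothing preserves the mean and shrinks the variance", {
  y <- white_noise_series(2048, 2, seed = 7)
  raw <- periodogram(y)
  hw <- 10
  sm <- smooth_periodogram(raw, half_width = hw)
  raw_diag <- spectral_density(raw)[, 1]
  sm_diag <- spectral_density(sm)[, 1]
  expect_equal(mean(sm_diag), mean(raw_diag), tolerance = 1e-6)
  ratio <- var(sm_diag) / var(raw_diag)
  expect_lt(abs(ratio - 1 / (2 * hw + 1)), 0.5 / (2 * hw + 1))
  # identity kernel with zero half-width is a no-op
  sm0 <- smooth_periodogram(raw, kernel = 1, half_width = 0)
  expect_equal(spectral_density(sm0), spectral_density(raw))
  expect_error(smooth_periodogram(raw, kernel = c(0, 0, 0), half_width = 1),
               "sum to zero")
})

test_that("smoothed AR(2) spectrum peaks at the prescribed frequency", {
  spec <- band_preset("alpha")
  z <- simulate_ar2_panel(spec, 2, 2000, seed = 21)
  y <- multivariate_series(unclass(z), 100)
  sm <- smooth_periodogram(periodogram(y), half_width = 7)
  power <- spectral_density(sm)
  freqs <- sm$freqs_hz
  half <- freqs <= 50
  for (i in 1:2) {
    peak <- freqs[half][which.max(power[half, i])]
    expect_lt(abs(peak - 10), 1)
  }
})

test_that("band coherence lies in [0, 1] with unit diagonal and detects
           independence", {
  y <- white_noise_series(4000, 3, seed = 5)
  sm <- smooth_periodogram(periodogram(y), half_width = 10)
  bc <- band_coherence(sm, c(8, 12))
  expect_equal(diag(bc$C), rep(1, 3))
  expect_equal(bc$C, t(bc$C))
  expect_true(all(bc$C >= 0 & bc$C <= 1))
  off <- bc$C[upper.tri(bc$C)]
  expect_lt(max(off), 0.15)  # independent channels: near-null coherence
  expect_error(band_coherence(sm, c(8)), "band_hz")
  expect_error(band_coherence(sm, c(200, 300)), "no Fourier bin")
})

test_that("coherence respects the mixing topology", {
  g <- circular_ladder(15)
  y <- simulate_network_series(g, band_preset("alpha"), K = 2,
                               n_time = 4000, noise_sd = 1, seed = 8)
  sm <- smooth_periodogram(periodogram(y))
  C <- band_coherence(sm, c(8, 12))$C
  d <- shortest_path_distances(g)
  near <- C[d == 1]
  far <- C[d == 4]
  expect_gt(mean(near), mean(far))
  expect_gt(mean(near > mean(far)), 0.9)
})

test_that("coherence distance transforms behave at the endpoints", {
  C <- matrix(c(1, 0.76, 0, 0.76, 1, 0.5, 0, 0.5, 1), 3, 3)
  D1 <- coherence_distance(C)
  expect_equal(D1[1, 2], 0.24)
  expect_equal(D1[1, 3], 1)
  expect_equal(diag(D1), rep(0, 3), ignore_attr = TRUE)
  D2 <- coherence_distance(C, transform = "sqrt_one_minus")
  expect_true(all(unclass(D2) >= unclass(D1)))  # sqrt dominates on (0,1)
  expect_error(coherence_distance(C * 2), "outside")
})

test_that("the series-to-distance pipeline is deterministic", {
  y <- simulate_network_series(circular_ladder(5), band_preset("alpha"),
                               n_time = 512, seed = 13)
  run <- function() {
    sm <- smooth_periodogram(periodogram(y), half_width = 5)
    coherence_distance(band_coherence(sm, c(8, 12)))
  }
  expect_identical(run(), run())
})

test_that("distance matrices round-trip through text files", {
  D <- coherence_distance(diag(3) * 0 + matrix(c(1, .5, .2, .5, 1, .3,
                                                 .2, .3, 1), 3, 3))
  path <- withr::local_tempfile(fileext = ".dist.tsv")
  write_distance_matrix(D, path)
  expect_equal(read_distance_matrix(path), unclass(D), tolerance = 1e-12,
               ignore_attr = TRUE)
})
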
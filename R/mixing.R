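#' Distance-decay mixing weights
#'
#' The observed channel `p` is a weighted sum of latent oscillations,
#' `Y_p(t) = sum_q W[p, q] Z_q(t) + eps_p(t)`, with weights decaying in the
#' hop distance and truncated at the cutoff `K`:
#' `W[p, q] = decay(d[p, q])` if `d[p, q] <= K`, else 0.  Channels close in
#' the graph therefore share many latents and are strongly dependent;
#' channels more than `2 K` hops apart share none and are independent.
#'
#' Decay functions: `inv_linear` `1 / (1 + d)` (the default used throughout),
#' `inv_quadratic` `1 / (1 + d^2)`, `exponential` `exp(-d)`.
#'
#' @param d distance matrix from [shortest_path_distances()].
#' @param K integer hop-count cutoff (>= 0); in practice 2 or 3.
#' @param decay decay function id.
#' @return the `P x P` weight matrix `W` (unit diagonal, symmetric).
#' @export
mixing_weights <- function(d, K = 2, decay = c("inv_linear", "inv_quadratic",
                                               "exponential")) {
  if (is.character(decay)) decay <- match.arg(decay)
  else stop_invalid("unknown decay id")
  K <- check_count(K, 0, "K")
  d <- as.matrix(d)
  fun <- switch(decay,
                inv_linear = function(x) 1 / (1 + x),
                inv_quadratic = function(x) 1 / (1 + x^2),
                exponential = function(x) exp(-x))
  W <- ifelse(d <= K, fun(d), 0)
  dimnames(W) <- NULL
  W
}

#' Theoretical channel correlations of the mixing model
#'
#' With unit-variance iid latents and independent noise, `Cov(Y) = W W' +
#' sigma_eps^2 I`, so for `p != q` the correlation is
#' `(W W')[p, q] / sqrt((W W' + s^2 I)[p, p] (W W' + s^2 I)[q, q])`, and 1 on
#' the diagonal.  Entries are exactly zero for channel pairs sharing no
#' latent process (hop distance `> 2 K`).
#'
#' @param W mixing weight matrix from [mixing_weights()].
#' @param noise_sd observation noise standard deviation `sigma_eps >= 0`.
#' @return the `P x P` correlation matrix.
#' @export
theoretical_correlation <- function(W, noise_sd = 0) {
  noise_sd <- check_number(noise_sd, "noise_sd", lower = 0)
  S <- tcrossprod(W)
  v <- diag(S) + noise_sd^2
  R <- S / sqrt(outer(v, v))
  diag(R) <- 1
  R
}

#' Simulate a multivariate series with a prescribed dependence topology
#'
#' Draws one latent AR(2) process per node of `g`, mixes them with the
#' distance-decay weights, and adds iid Gaussian observation noise:
#' `Y(t) = W Z(t) + eps(t)`.  Deterministic given `seed` (the latent panel
#' uses `seed`, the noise uses `seed + 10^6`).
#'
#' @param g a [dependence_graph()]; its node count sets the channel count.
#' @param band an `ar2_spec` shared by all latents.
#' @param K,decay mixing parameters, see [mixing_weights()].
#' @param n_time number of time points.
#' @param noise_sd observation noise sd (default 1: noise with the same
#'   variance as each unit-variance latent).
#' @param seed integer root seed.
#' @param burn_in warm-up samples for the latent recursions.
#' @return an object of class `multivariate_series`: list with `y`
#'   (`n_time x P` matrix), `sampling_rate_hz`, and the `W` used.
#' @export
simulate_network_series <- function(g, band, K = 2, decay = "inv_linear",
                                    n_time = 2000, noise_sd = 1, seed = 1,
                                    burn_in = 500) {
  stopifnot(inherits(g, "dependence_graph"), inherits(band, "ar2_spec"))
  noise_sd <- check_number(noise_sd, "noise_sd", lower = 0)
  seed <- check_count(seed, 0, "seed")
  d <- shortest_path_distances(g)
  W <- mixing_weights(d, K = K, decay = decay)
  z <- simulate_ar2_panel(band, n_series = g$n_nodes, n_time = n_time,
                          burn_in = burn_in, seed = seed)
  y <- z %*% t(W)
  if (noise_sd > 0) {
    set.seed(seed + 1000000L)
    y <- y + matrix(rnorm(length(y), sd = noise_sd), nrow(y), ncol(y))
  }
  multivariate_series(y, band$sampling_rate_hz, W = W)
}

#' Multivariate series container
#'
#' @param y `n_time x P` numeric matrix (rows = time, columns = channels).
#' @param sampling_rate_hz sampling rate in Hz.
#' @param W optional mixing weight matrix used to generate `y`.
#' @return an object of class `multivariate_series`.
#' @export
multivariate_series <- function(y, sampling_rate_hz, W = NULL) {
  y <- as.matrix(y)
  if (!is.numeric(y) || any(!is.finite(y)))
    stop_invalid("`y` must be a finite numeric matrix")
  if (ncol(y) < 2 || nrow(y) < 2)
    stop_invalid("`y` needs at least 2 channels and 2 time points")
  sampling_rate_hz <- check_number(sampling_rate_hz, "sampling_rate_hz",
                                   lower = 0, strict_lower = TRUE)
  structure(list(y = y, sampling_rate_hz = sampling_rate_hz, W = W),
            class = "multivariate_series")
}

#' @export
print.multivariate_series <- function(x, ...) {
  cat(sprintf("multivariate_series: %d time points x %d channels at %g Hz\n",
              nrow(x$y), ncol(x$y), x$sampling_rate_hz))
  invisible(x)
}

#' Noise level for a target signal-to-noise ratio
#'
#' `SNR = sigma_S^2 / sigma_N^2` with the signal variance taken as the
#' channel-averaged `mean(diag(W W'))`; returns the noise sd
#' `sigma_eps = sqrt(mean(diag(W W')) / target_snr)`.
#'
#' @param W mixing weight matrix.
#' @param target_snr desired SNR (> 0).
#' @return the observation-noise standard deviation.
#' @export
noise_sd_for_snr <- function(W, target_snr) {
  target_snr <- check_number(target_snr, "target_snr",
                             lower = 0, strict_lower = TRUE)
  sqrt(mean(rowSums(W^2)) / target_snr)
}

# delimited series I/O --------------------------------------------------

#' Read / write a multivariate series as delimited text
#'
#' Tab-separated values with header `ch1..chP`, one time point per row, and
#' the sampling rate recorded in a `# sampling_rate_hz:` comment line.
#'
#' @param x a [multivariate_series()].
#' @param path file path.
#' @param sampling_rate_hz override for files without the comment header.
#' @return the reader returns a [multivariate_series()]; the writer returns
#'   `path` invisibly.
#' @export
write_series <- function(x, path) {
  stopifnot(inherits(x, "multivariate_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz: %.10g", x$sampling_rate_hz), con)
  y <- x$y
  colnames(y) <- paste0("ch", seq_len(ncol(y)))
  utils::write.table(format(y, digits = 10, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path, sampling_rate_hz = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*sampling_rate_hz:", first)) {
    sr <- as.numeric(sub("^#\\s*sampling_rate_hz:\\s*", "", first))
    if (is.null(sampling_rate_hz)) sampling_rate_hz <- sr
  }
  if (is.null(sampling_rate_hz))
    stop_invalid("no sampling rate in '%s'; pass `sampling_rate_hz`", path)
  y <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  multivariate_series(as.matrix(y), sampling_rate_hz)
}
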
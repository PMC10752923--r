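#' Band-limited AR(2) specification
#'
#' An AR(2) process `Z(t) = phi1 Z(t-1) + phi2 Z(t-2) + W(t)` with complex
#' characteristic roots `M exp(+- i 2 pi psi)`, `psi = f / SR`, concentrates
#' its spectral power around the peak frequency `f`.  The coefficients follow
#' from the roots: `phi1 = (2 / M) cos(2 pi psi)` and `phi2 = -1 / M^2`.
#' Root magnitudes `M > 1` (both roots outside the unit circle) give a causal
#' stationary process; `M` close to 1 gives a sharp spectral peak.
#'
#' @param f peak frequency in Hz, strictly inside `(0, SR / 2)`.
#' @param SR sampling rate in Hz.
#' @param M root magnitude, dimensionless, `> 1` (default 1.05).
#' @param innovation_sd standard deviation of the white-noise innovations.
#' @return an object of class `ar2_spec` with fields `peak_freq_hz`,
#'   `sampling_rate_hz`, `root_magnitude`, `innovation_sd`, `phi1`, `phi2`.
#' @examples
#' ar2_from_peak(10, 100)           # alpha-band oscillation
#' @export
ar2_from_peak <- function(f, SR, M = 1.05, innovation_sd = 1) {
  SR <- check_number(SR, "SR", lower = 0, strict_lower = TRUE)
  f <- check_number(f, "f", lower = 0, upper = SR / 2,
                    strict_lower = TRUE, strict_upper = TRUE)
  M <- check_number(M, "M", lower = 1, strict_lower = TRUE)
  innovation_sd <- check_number(innovation_sd, "innovation_sd",
                                lower = 0, strict_lower = TRUE)
  psi <- f / SR
  spec <- structure(list(peak_freq_hz = f, sampling_rate_hz = SR,
                         root_magnitude = M, innovation_sd = innovation_sd,
                         phi1 = (2 / M) * cos(2 * pi * psi),
                         phi2 = -1 / M^2),
                    class = "ar2_spec")
  stopifnot(ar2_is_stationary(spec))  # guaranteed by construction
  spec
}

ar2_is_stationary <- function(spec) {
  with(spec, phi2 > -1 && phi2 + phi1 < 1 && phi2 - phi1 < 1)
}

#' @export
print.ar2_spec <- function(x, ...) {
  cat(sprintf(
    "ar2_spec: peak %.4g Hz at SR %.4g Hz (M = %.4g)\n  phi1 = %.6f, phi2 = %.6f, innovation sd = %.4g\n",
    x$peak_freq_hz, x$sampling_rate_hz, x$root_magnitude, x$phi1, x$phi2,
    x$innovation_sd))
  invisible(x)
}

#' Named band presets
#'
#' Canonical EEG-style frequency bands at a 100 Hz sampling rate: delta
#' (peak 2 Hz), theta (5 Hz), alpha (10 Hz) and beta (19.5 Hz).
#'
#' @param band one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`.
#' @param SR sampling rate in Hz (peaks scale with `SR / 100`).
#' @param M root magnitude passed to [ar2_from_peak()].
#' @return an `ar2_spec`.
#' @export
band_preset <- function(band = c("alpha", "delta", "theta", "beta"),
                        SR = 100, M = 1.05) {
  band <- match.arg(band)
  peak <- c(delta = 2, theta = 5, alpha = 10, beta = 19.5)[[band]]
  ar2_from_peak(peak * SR / 100, SR, M)
}

#' Theoretical AR(2) spectral density
#'
#' The spectral density `sigma^2 / |1 - phi1 e(-i 2 pi nu) -
#' phi2 e(-i 4 pi nu)|^2` at `nu = freq / SR`, of the raw (non-standardized)
#' process.  For `M` close to 1 the density is sharply peaked at the spec's
#' peak frequency.
#'
#' @param spec an `ar2_spec`.
#' @param freqs_hz frequencies in `[0, SR / 2]`.
#' @return positive numeric vector of power values.
#' @export
ar2_theoretical_spectrum <- function(spec, freqs_hz) {
  stopifnot(inherits(spec, "ar2_spec"))
  if (any(freqs_hz < 0 | freqs_hz > spec$sampling_rate_hz / 2))
    stop_invalid("`freqs_hz` must lie in [0, SR/2]")
  nu <- freqs_hz / spec$sampling_rate_hz
  denom <- Mod(1 - spec$phi1 * exp(-2i * pi * nu) -
                 spec$phi2 * exp(-4i * pi * nu))^2
  spec$innovation_sd^2 / denom
}

#' Stationary variance of an AR(2) process
#'
#' Closed form `sigma^2 (1 - phi2) / ((1 + phi2) ((1 - phi2)^2 - phi1^2))`,
#' positive for every spec produced by [ar2_from_peak()].  Used to
#' standardize simulated latents to unit theoretical variance.
#'
#' @param spec an `ar2_spec`.
#' @return the stationary process variance.
#' @export
ar2_stationary_variance <- function(spec) {
  stopifnot(inherits(spec, "ar2_spec"))
  with(spec, innovation_sd^2 * (1 - phi2) /
         ((1 + phi2) * ((1 - phi2)^2 - phi1^2)))
}

#' Simulate a panel of iid AR(2) latent series
#'
#' Runs `n_series` independent AR(2) recursions with Gaussian innovations
#' from a zero initial state, discards the first `burn_in` samples, and
#' divides each column by its theoretical stationary standard deviation so
#' that every latent has unit variance.  Each series uses the child seed
#' `seed + i` (for series `i`), so a panel is reproducible column by column
#' regardless of `n_series`.
#'
#' @param spec an `ar2_spec`.
#' @param n_series number of independent series (columns).
#' @param n_time number of retained time points (>= 2).
#' @param burn_in warm-up samples discarded from each series.
#' @param seed integer root seed.
#' @return a `n_time x n_series` matrix of class `latent_panel` with the
#'   spec attached as attribute `"spec"`.
#' @export
simulate_ar2_panel <- function(spec, n_series, n_time, burn_in = 500,
                               seed = 1) {
  stopifnot(inherits(spec, "ar2_spec"))
  if (!ar2_is_stationary(spec))
    stop_invalid("AR(2) spec is not stationary (phi1 = %g, phi2 = %g)",
                 spec$phi1, spec$phi2)
  n_series <- check_count(n_series, 1, "n_series")
  n_time <- check_count(n_time, 2, "n_time")
  burn_in <- check_count(burn_in, 0, "burn_in")
  seed <- check_count(seed, 0, "seed")
  total <- n_time + burn_in
  sd_stat <- sqrt(ar2_stationary_variance(spec))
  z <- matrix(0, n_time, n_series)
  for (i in seq_len(n_series)) {
    set.seed(seed + i)
    w <- rnorm(total, sd = spec$innovation_sd)
    zi <- stats::filter(w, c(spec$phi1, spec$phi2), method = "recursive",
                        init = c(0, 0))
    z[, i] <- as.numeric(zi)[(burn_in + 1):total] / sd_stat
  }
  structure(z, spec = spec, class = c("latent_panel", "matrix", "array"))
}
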
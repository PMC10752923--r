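#' Multivariate periodogram
#'
#' Fourier coefficients `d(w_k) = T^(-1/2) sum_t Y(t) exp(-i w_k t)` on the
#' grid `w_k = 2 pi k / T` (`k = 0..T-1`), after per-channel mean centering.
#' The raw periodogram `I(w_k) = d(w_k) d(w_k)*` is the rank-1 Hermitian
#' outer product of the coefficient vector; with this normalization it is
#' asymptotically unbiased for the spectral matrix.  The estimate is stored
#' as the `T x P` coefficient matrix; per-frequency `P x P` matrices are
#' realized on demand by [spectral_matrix()].
#'
#' @param y a [multivariate_series()] (at least 2 channels, `T >= 8`).
#' @return an object of class `spectral_estimate` (raw: identity kernel).
#' @export
periodogram <- function(y) {
  stopifnot(inherits(y, "multivariate_series"))
  if (ncol(y$y) < 2) stop_invalid("periodogram needs at least 2 channels")
  n_time <- nrow(y$y)
  if (n_time < 8) stop_invalid("periodogram needs T >= 8 time points")
  centered <- sweep(y$y, 2, colMeans(y$y))
  coef <- stats::mvfft(centered) / sqrt(n_time)
  structure(list(coef = coef,
                 freqs_hz = (seq_len(n_time) - 1) / n_time * y$sampling_rate_hz,
                 sampling_rate_hz = y$sampling_rate_hz,
                 kernel_id = "identity", half_width = 0L,
                 weights = 1),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf(
    "spectral_estimate: %d frequency bins x %d channels (kernel %s, half-width %d)\n",
    nrow(x$coef), ncol(x$coef), x$kernel_id, x$half_width))
  invisible(x)
}

#' Kernel-smoothed periodogram
#'
#' Frequency-wise convolution of the periodogram matrices with a normalized
#' non-negative kernel, with wrap-around at the ends of the Fourier grid:
#' `f_hat(w_k) = sum_j kernel_j I(w_(k+j))`.  Smoothing before forming
#' coherence is what makes the coherence estimate non-degenerate (the raw
#' rank-1 periodogram would give coherence identically 1) and guarantees the
#' smoothed matrices are Hermitian positive semidefinite.
#'
#' @param raw a raw `spectral_estimate` from [periodogram()].
#' @param kernel `"daniell"` (boxcar, the default) or a numeric vector of
#'   `2 * half_width + 1` non-negative weights (normalized internally).
#' @param half_width kernel half-width in frequency bins; default
#'   `ceiling(sqrt(T) / 2)`.
#' @return a smoothed `spectral_estimate`.
#' @export
smooth_periodogram <- function(raw, kernel = "daniell", half_width = NULL) {
  stopifnot(inherits(raw, "spectral_estimate"))
  n_bins <- nrow(raw$coef)
  if (is.null(half_width)) half_width <- ceiling(sqrt(n_bins) / 2)
  half_width <- check_count(half_width, 0, "half_width")
  if (is.character(kernel)) {
    kernel_id <- match.arg(kernel, "daniell")
    w <- rep(1, 2 * half_width + 1)
  } else {
    kernel_id <- "custom"
    w <- as.numeric(kernel)
    if (length(w) != 2 * half_width + 1)
      stop_invalid("custom kernel needs 2 * half_width + 1 weights")
    if (any(w < 0)) stop_invalid("kernel weights must be non-negative")
  }
  if (sum(w) <= 0) stop_invalid("kernel weights sum to zero")
  if (2 * half_width + 1 > n_bins)
    stop_invalid("kernel wider than the frequency grid")
  out <- raw
  out$kernel_id <- kernel_id
  out$half_width <- half_width
  out$weights <- w / sum(w)
  out
}

# Weighted Gram realization: f_hat(k) = sum_j a_j d_j d_j^*, with `a` a
# weight per Fourier bin (wrap-around indexing handled by the caller).
weighted_cross_spectrum <- function(coef, a) {
  nz <- which(a != 0)
  d <- coef[nz, , drop = FALSE]
  t(d * a[nz]) %*% Conj(d)
}

# kernel weights centered at bin k, wrapped onto 1..n_bins
kernel_weight_vector <- function(est, k) {
  n_bins <- nrow(est$coef)
  a <- numeric(n_bins)
  hw <- est$half_width
  idx <- ((k - 1 + (-hw:hw)) %% n_bins) + 1
  for (i in seq_along(idx)) a[idx[i]] <- a[idx[i]] + est$weights[i]
  a
}

#' Realize a spectral matrix at one frequency
#'
#' The `P x P` Hermitian (smoothed) cross-spectral matrix at the Fourier bin
#' nearest `freq_hz`.
#'
#' @param est a `spectral_estimate`.
#' @param freq_hz frequency in Hz, or `bin` an explicit 1-based bin index.
#' @param bin optional bin index overriding `freq_hz`.
#' @return a complex `P x P` matrix.
#' @export
spectral_matrix <- function(est, freq_hz = NULL, bin = NULL) {
  stopifnot(inherits(est, "spectral_estimate"))
  if (is.null(bin)) {
    if (is.null(freq_hz)) stop_invalid("give `freq_hz` or `bin`")
    bin <- which.min(abs(est$freqs_hz - freq_hz))
  }
  weighted_cross_spectrum(est$coef, kernel_weight_vector(est, bin))
}

#' Smoothed spectral densities of all channels
#'
#' The diagonal of the (smoothed) spectral matrix at every Fourier bin,
#' computed without realizing the `P x P` matrices.
#'
#' @param est a `spectral_estimate`.
#' @return a `T x P` matrix of non-negative power values.
#' @export
spectral_density <- function(est) {
  stopifnot(inherits(est, "spectral_estimate"))
  raw <- Mod(est$coef)^2
  if (est$half_width == 0L && length(est$weights) == 1L) return(raw)
  apply(raw, 2, function(col)
    as.numeric(stats::filter(col, est$weights, method = "convolution",
                             sides = 2, circular = TRUE)))
}

#' Frequency-band coherence matrix
#'
#' Averages the smoothed spectral matrices over the Fourier bins inside the
#' band, then forms the coherence `|f_bar[p, q]|^2 /
#' (f_bar[p, p] f_bar[q, q])`, a symmetric matrix in `[0, 1]` with unit
#' diagonal.  With `method = "per_bin"` the per-bin coherences are averaged
#' instead (a slower, optional variant).
#'
#' @param est a smoothed `spectral_estimate` (see [smooth_periodogram()]).
#' @param band_hz length-2 interval `[low, high]` in Hz; must contain at
#'   least one positive-frequency Fourier bin.
#' @param method band aggregation rule.
#' @return an object of class `band_coherence`: list with the matrix `C` and
#'   `band_hz`.
#' @export
band_coherence <- function(est, band_hz,
                           method = c("band_average", "per_bin")) {
  stopifnot(inherits(est, "spectral_estimate"))
  method <- match.arg(method)
  if (length(band_hz) != 2 || band_hz[1] > band_hz[2])
    stop_invalid("`band_hz` must be an interval [low, high]")
  nyquist <- est$sampling_rate_hz / 2
  bins <- which(est$freqs_hz >= band_hz[1] & est$freqs_hz <= band_hz[2] &
                  est$freqs_hz <= nyquist)
  if (length(bins) == 0)
    stop_invalid("band [%g, %g] Hz contains no Fourier bin",
                 band_hz[1], band_hz[2])
  coh_of <- function(f) {
    p <- Re(diag(f))
    C <- Mod(f)^2 / outer(p, p)
    diag(C) <- 1
    C
  }
  if (method == "band_average") {
    a <- numeric(nrow(est$coef))
    for (k in bins) a <- a + kernel_weight_vector(est, k)
    f_bar <- weighted_cross_spectrum(est$coef, a / length(bins))
    C <- coh_of(f_bar)
  } else {
    C <- 0
    for (k in bins) C <- C + coh_of(spectral_matrix(est, bin = k))
    C <- C / length(bins)
  }
  C <- (C + t(C)) / 2
  C <- pmin(pmax(C, 0), 1)  # clip floating-point residue at the endpoints
  structure(list(C = C, band_hz = as.numeric(band_hz)),
            class = "band_coherence")
}

#' @export
print.band_coherence <- function(x, ...) {
  cat(sprintf("band_coherence: %d channels, band [%g, %g] Hz\n",
              nrow(x$C), x$band_hz[1], x$band_hz[2]))
  invisible(x)
}

#' Coherence-based distance matrix
#'
#' Turns coherence into a distance with a decreasing transform:
#' `one_minus` `1 - C` (the default) or `sqrt_one_minus` `sqrt(1 - C)`.
#' The result has a zero diagonal, is symmetric, and lies in `[0, 1]`; it is
#' the input metric for [vr_persistence()].
#'
#' @param c a [band_coherence()] object, or a plain coherence matrix.
#' @param transform transform id.
#' @return a `P x P` distance matrix of class `coherence_distance` with the
#'   transform recorded as attribute `"transform"`.
#' @export
coherence_distance <- function(c, transform = c("one_minus",
                                                "sqrt_one_minus")) {
  transform <- match.arg(transform)
  C <- if (inherits(c, "band_coherence")) c$C else as.matrix(c)
  if (any(C < -1e-9 | C > 1 + 1e-9))
    stop_invalid("coherence entries outside [0, 1]: upstream estimate invalid")
  C <- pmin(pmax(C, 0), 1)
  D <- switch(transform, one_minus = 1 - C, sqrt_one_minus = sqrt(1 - C))
  D <- (D + t(D)) / 2
  diag(D) <- 0
  structure(D, transform = transform,
            class = c("coherence_distance", "matrix", "array"))
}

#' Read / write a distance matrix as delimited text
#'
#' Square tab-separated numeric matrix with a `ch1..chP` header row, directly
#' consumable by [vr_persistence()] or by external TDA tools.
#'
#' @param D a square numeric matrix.
#' @param path file path.
#' @return the reader returns a numeric matrix; the writer returns `path`
#'   invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  D <- as.matrix(D)
  colnames(D) <- paste0("ch", seq_len(ncol(D)))
  utils::write.table(D, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  D <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  dimnames(D) <- NULL
  if (nrow(D) != ncol(D)) stop_invalid("'%s' is not a square matrix", path)
  D
}
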
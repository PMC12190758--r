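#' @keywords internal
"_PACKAGE"

# Shared numeric helpers: FFT index shifts, Tukey windows, seeded
# substreams, trapezoidal integration.

#' Shift the zero-frequency component of an array to its centre
#'
#' Reorders each dimension so that the DC sample (index 1 in R's [stats::fft()]
#' convention) moves to index `floor(n/2) + 1`. `ifftshift()` is the exact
#' inverse and must be used before an inverse FFT of a centred spectrum.
#'
#' @param x A vector or array.
#' @return An object of the same shape with reordered elements.
#' @export
fftshift <- function(x) {
  .nd_shift(x, inverse = FALSE)
}

#' @rdname fftshift
#' @export
ifftshift <- function(x) {
  .nd_shift(x, inverse = TRUE)
}

.nd_shift <- function(x, inverse) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) {
    h <- if (inverse) floor(n / 2) else ceiling(n / 2)
    if (h == 0L || h == n) seq_len(n) else c((h + 1L):n, 1L:h)
  })
  out <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  if (is.null(dim(x))) out <- as.vector(out)
  dim(out) <- dim(x)
  out
}

#' Tukey (tapered-cosine) window
#'
#' Flat over the central `1 - r` fraction of the support with cosine tapers
#' of total fraction `r` at the two ends. `r = 0` gives a rectangular
#' window, `r = 1` a Hann window.
#'
#' @param n Number of samples.
#' @param r Taper fraction in `[0, 1]`.
#' @return Numeric vector of length `n` in `[0, 1]`.
#' @export
tukey_window <- function(n, r) {
  stopifnot(n >= 1, r >= 0, r <= 1)
  if (n == 1L) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  if (r > 0) {
    lo <- x < r / 2
    hi <- x > 1 - r / 2
    w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / r - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / r - 1)))
  }
  w
}

#' Derive a reproducible integer sub-seed
#'
#' All stochastic stages draw their randomness from one user seed; per-unit
#' substreams (per mouse, per tumor, per stage) are derived by counter so
#' that no stage depends on global RNG state left behind by another.
#'
#' @param seed Base integer seed.
#' @param counter Non-negative integer stream counter.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, counter) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(counter) * 7919 + 1
  as.integer(s %% 2147483647)
}

# Composite trapezoid on possibly non-uniform abscissae.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

# Trapezoid applied rowwise to a matrix of curves (rows = voxels).
trapz_rows <- function(x, ymat) {
  n <- length(x)
  dx <- x[-1] - x[-n]
  as.vector((ymat[, -1, drop = FALSE] + ymat[, -n, drop = FALSE]) %*% (dx / 2))
}

# Smooth ramp used by the radial phantom profiles: 0 below `lo`,
# 1 above `hi`, C1-continuous cubic in between.
smoothstep <- function(u, lo, hi) {
  t <- pmin(1, pmax(0, (u - lo) / (hi - lo)))
  t * t * (3 - 2 * t)
}

# Inverse of the cubic smoothstep kernel on [0, 1].
smoothstep_inv <- function(s) {
  stopifnot(all(s >= 0 & s <= 1))
  vapply(s, function(si) {
    if (si <= 0) return(0)
    if (si >= 1) return(1)
    stats::uniroot(function(t) t * t * (3 - 2 * t) - si, c(0, 1),
                   tol = 1e-12)$root
  }, numeric(1))
}
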
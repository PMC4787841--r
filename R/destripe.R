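#' Daubechies scaling filter
#'
#' Builds the orthonormal Daubechies scaling filter with `n_moments`
#' vanishing moments (length `2 * n_moments`) by spectral factorization:
#' the roots of the binomial half-band polynomial are computed with
#' [polyroot()], the minimum-phase (inside-unit-circle) roots are kept, and
#' the filter is assembled as `(1 + z)^N` times the retained root factors,
#' normalized to sum `sqrt(2)`.
#'
#' @param n_moments Number of vanishing moments (e.g. 15 for "Daubechies 15").
#' @return Numeric vector of `2 * n_moments` filter taps.
#' @export
daubechies_filter <- function(n_moments) {
  N <- as.integer(n_moments)
  if (N < 1L) stop("n_moments must be >= 1")
  if (N == 1L) return(rep(1 / sqrt(2), 2))
  # P(y) = sum_{k=0}^{N-1} choose(N-1+k, k) y^k ; roots in y
  py <- choose(N - 1 + 0:(N - 1), 0:(N - 1))
  yroots <- polyroot(py)
  # each y maps to z^2 - (2 - 4y) z + 1 = 0; keep |z| < 1
  zroots <- unlist(lapply(yroots, function(y) {
    b <- 2 - 4 * y
    disc <- sqrt(as.complex(b^2 - 4))
    z <- c((b + disc) / 2, (b - disc) / 2)
    z[which.min(Mod(z))]
  }))
  # h(z) = (1 + z)^N * prod (z - z_i), expanded by convolution
  h <- 1
  for (i in seq_len(N)) h <- convolve_poly(h, c(1, 1))
  for (z in zroots) h <- convolve_poly(h, c(-z, 1))
  h <- Re(h)
  h * sqrt(2) / sum(h)
}

convolve_poly <- function(a, b) {
  out <- rep(0 + 0i, length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i + seq_along(b) - 1L] <- out[i + seq_along(b) - 1L] + a[i] * b
  }
  out
}

# quadrature mirror (wavelet) filter from a scaling filter
qmf <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1L)
}

# one periodized analysis step along columns of X (each column is a signal
# of even length): returns approximation and detail halves
dwt_step_cols <- function(X, h) {
  g <- qmf(h)
  n <- nrow(X)
  if (n %% 2L != 0L) stop("periodized transform needs even length")
  half <- n %/% 2L
  A <- matrix(0, half, ncol(X))
  D <- matrix(0, half, ncol(X))
  base <- 2L * (seq_len(half) - 1L)
  for (m in seq_along(h)) {
    idx <- (base + m - 1L) %% n + 1L
    A <- A + h[m] * X[idx, , drop = FALSE]
    D <- D + g[m] * X[idx, , drop = FALSE]
  }
  list(A = A, D = D)
}

# inverse of dwt_step_cols (exact, the transform is orthogonal)
idwt_step_cols <- function(A, D, h) {
  g <- qmf(h)
  half <- nrow(A)
  n <- 2L * half
  X <- matrix(0, n, ncol(A))
  base <- 2L * (seq_len(half) - 1L)
  for (m in seq_along(h)) {
    # within one tap the target rows are distinct, so this scatter is safe
    idx <- (base + m - 1L) %% n + 1L
    X[idx, ] <- X[idx, , drop = FALSE] + h[m] * A + g[m] * D
  }
  X
}

# one 2-D separable analysis step; names: first letter = along-angle (rows)
# band, second = along-bin (columns) band
dwt2_step <- function(m, h) {
  rowpass <- dwt_step_cols(m, h)                    # along rows (angle axis)
  LA <- rowpass$A; HA <- rowpass$D
  Lc <- dwt_step_cols(t(LA), h)
  Hc <- dwt_step_cols(t(HA), h)
  list(LL = t(Lc$A), LH = t(Lc$D), HL = t(Hc$A), HH = t(Hc$D))
}

#' Wavelet–Fourier destriping parameters
#'
#' @param levels Wavelet decomposition depth (>= 1).
#' @param sigma Standard deviation (in angle-frequency samples) of the
#'   high-pass Gaussian damping filter; larger removes a wider low-frequency
#'   band, i.e. stripes that vary more along the angle.
#' @param wavelet Wavelet name, `"db<N>"` or `"Daubechies <N>"`.
#' @return A `destripe_params`.
#' @export
destripe_params <- function(levels = 2L, sigma = 3.5, wavelet = "db15") {
  if (levels < 1L) stop("levels must be >= 1")
  if (sigma <= 0) stop("sigma must be > 0")
  nm <- regmatches(wavelet, regexpr("[0-9]+", wavelet))
  if (!length(nm)) stop("cannot parse wavelet name: ", wavelet)
  structure(list(levels = as.integer(levels), sigma = as.numeric(sigma),
                 wavelet = wavelet, n_moments = as.integer(nm)),
            class = "destripe_params")
}

#' Wavelet–Fourier sinogram destriping
#'
#' Classic stripe suppression by combined wavelet and Fourier filtering:
#' the sinogram is decomposed to `levels` with a separable periodized
#' Daubechies transform; at every level the stripe band (low-pass along the
#' angle axis, high-pass across detector bins — where angle-constant narrow
#' lines concentrate) is Fourier-transformed along the angle axis and
#' multiplied by the high-pass Gaussian `1 - exp(-k^2 / (2 sigma^2))`
#' (which zeroes the angle-constant component, `g(0) = 0`); the sinogram is
#' then rebuilt by the inverse transform. Odd-sized inputs are
#' replicate-padded to a multiple of `2^levels` and cropped on return.
#'
#' @param sino A [sinogram()] (or plain matrix, angles in rows).
#' @param p A [destripe_params()].
#' @return The destriped sinogram, same class and shape as the input.
#' @export
munch_destripe <- function(sino, p = destripe_params()) {
  stopifnot(inherits(p, "destripe_params"))
  m <- if (inherits(sino, "sinogram")) unclass_matrix(sino) else as.matrix(sino)
  if (min(dim(m)) < 2L^p$levels) stop("decomposition too deep for this sinogram")
  h <- daubechies_filter(p$n_moments)

  blk <- 2L^p$levels
  pad_r <- (blk - nrow(m) %% blk) %% blk
  pad_c <- (blk - ncol(m) %% blk) %% blk
  mp <- m
  if (pad_r > 0L) mp <- rbind(mp, mp[rep(nrow(mp), pad_r), , drop = FALSE])
  if (pad_c > 0L) mp <- cbind(mp, mp[, rep(ncol(mp), pad_c), drop = FALSE])

  filtered <- destripe_recurse(mp, h, p$levels, p$sigma)
  out <- filtered[seq_len(nrow(m)), seq_len(ncol(m)), drop = FALSE]
  if (inherits(sino, "sinogram")) sinogram(out, sino_geometry(sino)) else out
}

destripe_recurse <- function(m, h, levels, sigma) {
  b <- dwt2_step(m, h)
  b$LH <- fourier_damp_stripe_band(b$LH, sigma)
  if (levels > 1L) b$LL <- destripe_recurse(b$LL, h, levels - 1L, sigma)
  inv_dwt2_step(b, h)
}

# damp low angle-frequencies of a band (columns are along-angle signals
# after transposition: rows index angle here)
fourier_damp_stripe_band <- function(band, sigma) {
  n <- nrow(band)
  sp <- stats::mvfft(band)
  k <- c(0:(n %/% 2L), if (n > 1L) -((n - n %/% 2L - 1L):1L)) # signed freqs
  gain <- 1 - exp(-k^2 / (2 * sigma^2))
  Re(stats::mvfft(sp * gain, inverse = TRUE)) / n
}

inv_dwt2_step <- function(bands, h) {
  LA <- t(idwt_step_cols(t(bands$LL), t(bands$LH), h))
  HA <- t(idwt_step_cols(t(bands$HL), t(bands$HH), h))
  idwt_step_cols(LA, HA, h)
}
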
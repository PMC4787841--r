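#' Forward projection (discrete Radon transform)
#'
#' Computes discrete line integrals of a square slice along each geometry
#' angle with a Joseph-style linear-interpolation ray driver: each ray is
#' sampled once per crossed row (or column, whichever axis is better aligned
#' with the ray), and samples are weighted by the per-step path length.
#' The operator is linear in the image; rays leaving the image support
#' contribute zero.
#'
#' @param img An [image2d()] (or plain square matrix).
#' @param geom A [projection_geometry()].
#' @return A [sinogram()] with one row per angle.
#' @seealso [backproject()] for the exact adjoint.
#' @export
project <- function(img, geom) {
  if (!inherits(geom, "projection_geometry")) {
    stop("geom must be a projection_geometry")
  }
  img <- as.matrix(img)
  if (nrow(img) != ncol(img)) stop("image must be square")
  v <- joseph_project_cpp(img, geom$angles_rad, geom$n_bins,
                          geom$rotation_center)
  sinogram(v, geom)
}

#' Back-projection (exact adjoint of the forward projector)
#'
#' Smears each sinogram value back along its ray using the same
#' interpolation weights as [project()], so that
#' `sum(project(x) * y) == sum(x * backproject(y))` to rounding.
#'
#' @param sino A [sinogram()].
#' @param n Side length of the output image. Defaults to the bin count.
#' @return An [image2d()].
#' @export
backproject <- function(sino, n = sino_geometry(sino)$n_bins) {
  g <- sino_geometry(sino)
  v <- joseph_backproject_cpp(unclass_matrix(sino), g$angles_rad,
                              as.integer(n), g$rotation_center)
  image2d(v)
}

unclass_matrix <- function(x) {
  x <- unclass(x)
  attr(x, "geometry") <- NULL
  attr(x, "pixel_size") <- NULL
  x
}

#' Band-limited discrete ramp filter
#'
#' Convolves each sinogram row with the band-limited spatial-domain ramp
#' kernel: value 1/4 at lag 0, `-1/(pi^2 n^2)` at odd lags n, 0 at even lags.
#' The convolution is carried out by FFT with zero-padding to at least twice
#' the bin count, so it is linear (not circular). The kernel's own DC gain is
#' small but nonzero; by default it is kept (`preserve_dc = TRUE`), so a
#' constant row maps to a nonzero constant. The filter acts on each angle row
#' independently and is self-adjoint (the kernel is even).
#'
#' @param sino A [sinogram()].
#' @param preserve_dc Keep the kernel's nonzero zero-frequency gain (default).
#'   If `FALSE` the zero-frequency gain is forced to 0.
#' @return A [sinogram()] of the same shape.
#' @export
ramp_filter <- function(sino, preserve_dc = TRUE) {
  g <- sino_geometry(sino)
  v <- ramp_filter_rows(unclass_matrix(sino), preserve_dc = preserve_dc)
  sinogram(v, g)
}

# rows of `m` filtered with the band-limited ramp kernel; plain-matrix core
ramp_filter_rows <- function(m, preserve_dc = TRUE) {
  nb <- ncol(m)
  gain <- ramp_freq_gain(nb, preserve_dc)
  npad <- length(gain)
  padded <- matrix(0, nrow(m), npad)
  padded[, seq_len(nb)] <- m
  # FFT along rows: mvfft works on columns, so transpose
  sp <- stats::mvfft(t(padded))
  sp <- sp * gain
  out <- Re(stats::mvfft(sp, inverse = TRUE)) / npad
  t(out)[, seq_len(nb), drop = FALSE]
}

# frequency response of the zero-padded band-limited ramp kernel
ramp_freq_gain <- function(n_bins, preserve_dc = TRUE) {
  npad <- 2L^ceiling(log2(max(2L * n_bins, 64L)))
  lag <- c(0:(npad / 2L), (-npad / 2L + 1L):(-1L))
  h <- numeric(npad)
  h[lag == 0L] <- 0.25
  odd <- lag %% 2L != 0L
  h[odd] <- -1 / (pi^2 * lag[odd]^2)
  gain <- Re(stats::fft(h))
  if (!preserve_dc) gain[1L] <- 0
  gain
}

#' Filtered back-projection
#'
#' Standard FBP: ramp-filter every projection row, back-project, and scale by
#' the angular step `pi / n_angles`.
#'
#' @inheritParams backproject
#' @return An [image2d()] reconstruction.
#' @export
fbp <- function(sino, n = sino_geometry(sino)$n_bins) {
  g <- sino_geometry(sino)
  bp <- backproject(ramp_filter(sino), n = n)
  image2d(unclass_matrix(bp) * (pi / length(g$angles_rad)))
}
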
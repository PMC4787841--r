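#' Parallel-beam projection geometry
#'
#' Describes a 2-D parallel-beam acquisition: the projection angles, the
#' number of detector bins and the (possibly fractional) detector bin onto
#' which the rotation axis projects.
#'
#' @param angles_rad Numeric vector of projection angles in radians, strictly
#'   increasing, in `[0, pi)`.
#' @param n_bins Integer, number of detector bins (>= 2).
#' @param rotation_center Real-valued center bin, 0-based, in
#'   `[0, n_bins - 1]`. Defaults to `(n_bins - 1) / 2`.
#' @return An object of class `projection_geometry`.
#' @examples
#' geom <- projection_geometry(seq(0, pi, length.out = 91)[-91], 64)
#' @export
projection_geometry <- function(angles_rad, n_bins,
                                rotation_center = (n_bins - 1) / 2) {
  angles_rad <- as.numeric(angles_rad)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (length(angles_rad) < 1L || anyNA(angles_rad)) {
    stop("angles_rad must be a non-empty numeric vector")
  }
  if (any(diff(angles_rad) <= 0)) stop("angles must be strictly increasing")
  if (any(angles_rad < 0) || any(angles_rad >= pi)) {
    stop("angles must lie in [0, pi)")
  }
  if (rotation_center < 0 || rotation_center > n_bins - 1) {
    stop("rotation_center must lie in [0, n_bins - 1]")
  }
  structure(
    list(angles_rad = angles_rad, n_bins = n_bins,
         rotation_center = as.numeric(rotation_center)),
    class = "projection_geometry"
  )
}

#' Evenly spaced half-turn geometry
#'
#' Convenience constructor: `n_angles` angles evenly covering `[0, pi)`.
#'
#' @param n_angles Number of projection angles.
#' @inheritParams projection_geometry
#' @return A `projection_geometry`.
#' @export
half_turn_geometry <- function(n_angles, n_bins,
                               rotation_center = (n_bins - 1) / 2) {
  projection_geometry(seq(0, pi, length.out = n_angles + 1L)[seq_len(n_angles)],
                      n_bins, rotation_center)
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf("parallel-beam geometry: %d angles in [%.4f, %.4f] rad, %d bins, center %.2f\n",
              length(x$angles_rad), min(x$angles_rad), max(x$angles_rad),
              x$n_bins, x$rotation_center))
  invisible(x)
}

#' Square reconstruction slice
#'
#' @param pixels N x N numeric matrix of finite values; rows index y, columns x.
#' @param pixel_size Pixel pitch in arbitrary units (default 1).
#' @return An object of class `image2d` (a matrix with attributes).
#' @export
image2d <- function(pixels, pixel_size = 1) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) != ncol(pixels)) stop("image must be square")
  if (!all(is.finite(pixels))) stop("image must contain only finite values")
  structure(pixels, pixel_size = pixel_size, class = c("image2d", "matrix", "array"))
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("image2d: %d x %d, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Sinogram: projection data with its geometry
#'
#' @param values n_angles x n_bins numeric matrix; row i is the projection at
#'   `geometry$angles_rad[i]`.
#' @param geometry A [projection_geometry()].
#' @return An object of class `sinogram` (a matrix with a `geometry` attribute).
#' @export
sinogram <- function(values, geometry) {
  values <- as.matrix(values)
  if (!inherits(geometry, "projection_geometry")) {
    stop("geometry must be a projection_geometry")
  }
  if (nrow(values) != length(geometry$angles_rad)) {
    stop("sinogram row count must equal the number of angles")
  }
  if (ncol(values) != geometry$n_bins) {
    stop("sinogram column count must equal n_bins")
  }
  if (!all(is.finite(values))) stop("sinogram must contain only finite values")
  structure(values, geometry = geometry, class = c("sinogram", "matrix", "array"))
}

#' @export
print.sinogram <- function(x, ...) {
  g <- attr(x, "geometry")
  cat(sprintf("sinogram: %d angles x %d bins, range [%.4g, %.4g]\n",
              nrow(x), g$n_bins, min(x), max(x)))
  invisible(x)
}

sino_geometry <- function(sino) {
  g <- attr(sino, "geometry")
  if (is.null(g)) stop("sinogram is missing its geometry attribute")
  g
}
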
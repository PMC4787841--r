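#' Read and write slices and sinograms as 32-bit TIFF
#'
#' Samples are stored at 32-bit depth; because the TIFF layer stores data on
#' a \[0, 1\] scale, values are mapped affinely on write and the original
#' range is recorded in a YAML sidecar `<file>.yaml`, so arbitrary value
#' ranges round-trip to better than single precision. For sinograms the
#' sidecar also carries the acquisition geometry (explicit angle list, bin
#' count, rotation center), which `read_sinogram_tiff` uses to rebuild the
#' [sinogram()].
#'
#' @param img,sino Object to write.
#' @param file Path of the TIFF file.
#' @return Readers return the reconstructed object; writers return `file`
#'   invisibly.
#' @export
write_image_tiff <- function(img, file) {
  sc <- tiff_scale_write(as.matrix(img), file)
  yaml::write_yaml(list(value_min = sc$lo, value_max = sc$hi),
                   paste0(file, ".yaml"))
  invisible(file)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(file) {
  meta <- yaml::read_yaml(paste0(file, ".yaml"))
  image2d(tiff_scale_read(file, meta))
}

#' @rdname write_image_tiff
#' @export
write_sinogram_tiff <- function(sino, file) {
  g <- sino_geometry(sino)
  sc <- tiff_scale_write(unclass_matrix(sino), file)
  yaml::write_yaml(list(value_min = sc$lo, value_max = sc$hi,
                        angles_rad = g$angles_rad, n_bins = g$n_bins,
                        rotation_center = g$rotation_center),
                   paste0(file, ".yaml"))
  invisible(file)
}

#' @rdname write_image_tiff
#' @export
read_sinogram_tiff <- function(file) {
  meta <- yaml::read_yaml(paste0(file, ".yaml"))
  geom <- projection_geometry(as.numeric(unlist(meta$angles_rad)),
                              meta$n_bins, meta$rotation_center)
  sinogram(tiff_scale_read(file, meta), geom)
}

tiff_scale_write <- function(m, file) {
  lo <- min(m); hi <- max(m)
  scaled <- if (hi > lo) (m - lo) / (hi - lo) else m * 0
  tiff::writeTIFF(scaled, file, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  list(lo = lo, hi = hi)
}

tiff_scale_read <- function(file, meta) {
  m <- as.matrix(tiff::readTIFF(file, as.is = FALSE))
  meta$value_min + m * (meta$value_max - meta$value_min)
}

#' Geometry configuration files
#'
#' A [projection_geometry()] serialized as YAML: either an explicit
#' `angles_rad` list or an `n_angles` count (expanded to an even half-turn
#' coverage), plus `n_bins` and `rotation_center`.
#'
#' @param geom A [projection_geometry()].
#' @param file Path of the YAML file.
#' @return `read_geometry` returns a [projection_geometry()].
#' @export
write_geometry <- function(geom, file) {
  yaml::write_yaml(list(angles_rad = geom$angles_rad, n_bins = geom$n_bins,
                        rotation_center = geom$rotation_center), file)
  invisible(file)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(file) {
  y <- yaml::read_yaml(file)
  rc <- if (is.null(y$rotation_center)) (y$n_bins - 1) / 2 else y$rotation_center
  if (!is.null(y$angles_rad)) {
    projection_geometry(as.numeric(unlist(y$angles_rad)), y$n_bins, rc)
  } else if (!is.null(y$n_angles)) {
    projection_geometry(
      seq(0, pi, length.out = y$n_angles + 1L)[seq_len(y$n_angles)],
      y$n_bins, rc)
  } else {
    stop("geometry file needs angles_rad or n_angles")
  }
}

#' Plain-text array, ring-vector and energy-trace files
#'
#' `write_array_txt`/`read_array_txt` store a numeric matrix as
#' tab-separated text. `write_ring_vector` writes one value per line in bin
#' order. `write_energy_trace` writes the per-iteration energy components of
#' a reconstruction as CSV with columns
#' iteration, fidelity, regularization, ring_l1, total.
#'
#' @param m Numeric matrix.
#' @param u Ring vector.
#' @param result A `recon_result`.
#' @param file Output path.
#' @return Readers return the parsed object; writers return `file` invisibly.
#' @export
write_array_txt <- function(m, file) {
  utils::write.table(as.matrix(m), file, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' @rdname write_array_txt
#' @export
read_array_txt <- function(file) {
  as.matrix(utils::read.table(file, sep = "\t", header = FALSE))
}

#' @rdname write_array_txt
#' @export
write_ring_vector <- function(u, file) {
  writeLines(formatC(u, format = "g", digits = 17), file)
  invisible(file)
}

#' @rdname write_array_txt
#' @export
read_ring_vector <- function(file) {
  as.numeric(readLines(file))
}

#' @rdname write_array_txt
#' @export
write_energy_trace <- function(result, file) {
  utils::write.csv(result$energy_components, file, row.names = FALSE)
  invisible(file)
}
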
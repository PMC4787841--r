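#' Synthetic phantoms
#'
#' Deterministic (seeded) square test slices:
#' * `piecewise_disks` — a uniform support disk carrying a handful of
#'   constant-intensity disks; the piecewise-constant regime where TV
#'   regularization is at its best.
#' * `textured` — the same layout plus a smooth oscillatory texture inside
#'   the support, harder for a piecewise-constant prior.
#' * `with_ring_features` — the piecewise phantom plus a filled black disk
#'   and a thin bright annulus. These are genuine features of the object:
#'   ring-correction methods must preserve them while removing artifact
#'   rings. The annulus and disk pixel masks are attached as attributes
#'   `annulus_mask` and `disk_mask`.
#'
#' @param kind One of `"piecewise_disks"`, `"textured"`,
#'   `"with_ring_features"`.
#' @param n Side length (>= 16).
#' @param seed Integer seed; the output is identical across runs for a fixed
#'   seed.
#' @return An [image2d()].
#' @export
make_phantom <- function(kind = c("piecewise_disks", "textured",
                                  "with_ring_features"),
                         n = 128L, seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 16L) stop("n must be >= 16")
  c0 <- (n - 1) / 2
  xx <- matrix(rep(seq_len(n) - 1 - c0, each = n), n, n)   # column coord
  yy <- matrix(rep(seq_len(n) - 1 - c0, times = n), n, n)  # row coord
  rr <- sqrt(xx^2 + yy^2)

  img <- withr::with_seed(as.integer(seed), {
    m <- matrix(0, n, n)
    support <- rr <= 0.46 * n
    m[support] <- 0.2
    for (k in seq_len(6L)) {
      cx <- stats::runif(1, -0.28, 0.28) * n
      cy <- stats::runif(1, -0.28, 0.28) * n
      rad <- stats::runif(1, 0.05, 0.14) * n
      val <- stats::runif(1, 0.3, 1)
      m[(xx - cx)^2 + (yy - cy)^2 <= rad^2] <- val
    }
    m[!support] <- 0
    if (kind == "textured") {
      tex <- matrix(0, n, n)
      for (k in seq_len(4L)) {
        fx <- stats::runif(1, 2, 6) * 2 * pi / n
        fy <- stats::runif(1, 2, 6) * 2 * pi / n
        ph <- stats::runif(2, 0, 2 * pi)
        tex <- tex + sin(fx * xx + ph[1]) * sin(fy * yy + ph[2])
      }
      m[support] <- m[support] + 0.08 * tex[support]
      m <- pmax(m, 0)
    }
    m
  })

  if (kind == "with_ring_features") {
    # the black disk stays strictly inside the annulus radius
    disk <- (xx - 0.15 * n)^2 + (yy + 0.1 * n)^2 <= (0.07 * n)^2
    annulus <- abs(rr - 0.3 * n) <= 1.2
    img[disk] <- 0
    img[annulus] <- 0.9
    out <- image2d(img)
    attr(out, "disk_mask") <- disk
    attr(out, "annulus_mask") <- annulus
    return(out)
  }
  image2d(img)
}

#' Stripe (spurious detector line) specification
#'
#' @param bin 0-based detector bin index of the left edge of the stripe.
#' @param amplitude Additive amplitude. For `mode = "constant"` the same
#'   value is added at every angle; for `mode = "variable"` it is modulated
#'   by a smooth seeded per-angle profile (low-order random cosine series).
#'   A numeric vector of per-angle amplitudes may also be given directly.
#' @param width Stripe width in bins (>= 1; a band when > 1).
#' @param mode `"constant"` or `"variable"`.
#' @return A `stripe_spec`.
#' @export
stripe_spec <- function(bin, amplitude, width = 1L,
                        mode = c("constant", "variable")) {
  mode <- match.arg(mode)
  if (width < 1L) stop("width must be >= 1")
  structure(list(bin = as.integer(bin), amplitude = amplitude,
                 width = as.integer(width), mode = mode),
            class = "stripe_spec")
}

#' Inject spurious stripes into a sinogram
#'
#' Adds the corruption described by a list of [stripe_spec()]s. Constant
#' stripes add the same amplitude to every angle at the given bins; variable
#' stripes modulate the amplitude per angle with a smooth seeded profile
#' `a * (1 + sum of low-order random cosines)`. The injected field is
#' returned as attribute `corruption`, so the clean sinogram is recoverable
#' by subtraction; the affected bins are in attribute `stripe_bins`.
#'
#' @param sino A [sinogram()].
#' @param stripes List of [stripe_spec()]s (a single spec is accepted).
#' @param seed Integer seed for the variable-intensity profiles.
#' @return A corrupted [sinogram()].
#' @export
inject_stripes <- function(sino, stripes, seed = 1L) {
  if (inherits(stripes, "stripe_spec")) stripes <- list(stripes)
  g <- sino_geometry(sino)
  na <- length(g$angles_rad)
  field <- matrix(0, na, g$n_bins)
  bins_hit <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (sp in stripes) {
      bins <- sp$bin + seq_len(sp$width) - 1L
      if (any(bins < 0L) || any(bins >= g$n_bins)) {
        stop("stripe bin out of range")
      }
      for (b in bins) {
        prof <- if (is.numeric(sp$amplitude) && length(sp$amplitude) == na) {
          sp$amplitude
        } else if (sp$mode == "constant") {
          rep(sp$amplitude, na)
        } else {
          ang <- seq_len(na) / na
          modc <- stats::rnorm(4, 0, 0.15)
          mods <- stats::rnorm(4, 0, 0.15)
          mod <- rep(1, na)
          for (j in 1:4) {
            mod <- mod + modc[j] * cos(2 * pi * j * ang) +
              mods[j] * sin(2 * pi * j * ang)
          }
          sp$amplitude * mod
        }
        field[, b + 1L] <- field[, b + 1L] + prof
      }
      bins_hit <- c(bins_hit, bins)
    }
  })
  out <- sinogram(unclass_matrix(sino) + field, g)
  attr(out, "corruption") <- field
  attr(out, "stripe_bins") <- sort(unique(bins_hit))
  out
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` with `peak = max(ref) - min(ref)`. Identical
#' images give `Inf`.
#'
#' @param ref Reference image (matrix).
#' @param test Test image of the same shape.
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test) {
  ref <- as.matrix(ref); test <- as.matrix(test)
  if (!all(dim(ref) == dim(test))) stop("psnr: shape mismatch")
  mse <- mean((ref - test)^2)
  if (mse == 0) return(Inf)
  peak <- max(ref) - min(ref)
  10 * log10(peak^2 / mse)
}

#' Packaged corruption scenarios
#'
#' Three standard test fixtures of increasing difficulty, regenerated
#' bit-identically from the seed:
#' * case 1 — piecewise-constant phantom; six constant stripes of amplitude
#'   5% of the sinogram maximum at seeded bins.
#' * case 2 — same phantom; six variable-intensity stripes (smooth seeded
#'   per-angle modulation) of the same base amplitude.
#' * case 3 — phantom with genuine ring-shaped features (black disk + thin
#'   annulus); variable-intensity stripes up to 3 bins wide.
#'
#' @param case 1, 2 or 3.
#' @param n Phantom side length (default 128).
#' @param n_angles Number of projection angles over the half turn
#'   (default 180).
#' @param seed Integer seed.
#' @return List with `phantom`, `geometry`, `clean` (sinogram of the
#'   phantom), `corrupt` (stripe-injected sinogram), `stripes` (the specs),
#'   `stripe_bins` (0-based bins hit).
#' @export
ring_scenario <- function(case = 1L, n = 128L, n_angles = 180L, seed = 1L) {
  case <- as.integer(case)
  if (!case %in% 1:3) stop("case must be 1, 2 or 3")
  kind <- if (case == 3L) "with_ring_features" else "piecewise_disks"
  phantom <- make_phantom(kind, n = n, seed = seed)
  geom <- half_turn_geometry(n_angles, n)
  clean <- project(phantom, geom)
  amp <- 0.05 * max(clean)
  lo <- round(0.15 * n); hi <- round(0.85 * n)
  bins <- withr::with_seed(as.integer(seed) + 1000L,
                           sort(sample(lo:hi, 6L)))
  widths <- if (case == 3L) {
    withr::with_seed(as.integer(seed) + 2000L, sample(1:3, 6L, replace = TRUE))
  } else rep(1L, 6L)
  mode <- if (case == 1L) "constant" else "variable"
  stripes <- lapply(seq_len(6L), function(i) {
    stripe_spec(bins[i], amp, width = widths[i], mode = mode)
  })
  corrupt <- inject_stripes(clean, stripes, seed = seed + 3000L)
  list(phantom = phantom, geometry = geom, clean = clean, corrupt = corrupt,
       stripes = stripes, stripe_bins = attr(corrupt, "stripe_bins"))
}
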
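#' Isotropic total variation of an image
#'
#' Sum over pixels of `sqrt(dx^2 + dy^2)` with forward differences and
#' replicate (Neumann) boundary: the difference past the last row/column is
#' zero. A 1 x N (or N x 1) input degenerates cleanly to the 1-D case
#' `sum(abs(diff(x)))`.
#'
#' @param img Numeric matrix (an [image2d()] or plain matrix).
#' @return Nonnegative scalar.
#' @export
tv_norm <- function(img) {
  img <- as.matrix(img)
  d <- image_gradient(img)
  sum(sqrt(d$dx^2 + d$dy^2))
}

# forward-difference gradient with zero difference at the last row/column
image_gradient <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  dx <- matrix(0, nr, nc)   # along columns (x)
  dy <- matrix(0, nr, nc)   # along rows (y)
  if (nc > 1L) dx[, -nc] <- m[, -1L, drop = FALSE] - m[, -nc, drop = FALSE]
  if (nr > 1L) dy[-nr, ] <- m[-1L, , drop = FALSE] - m[-nr, , drop = FALSE]
  list(dx = dx, dy = dy)
}

# negative adjoint of image_gradient: <grad m, (dx,dy)> = -<m, div(dx,dy)>
image_divergence <- function(dx, dy) {
  nr <- nrow(dx); nc <- ncol(dx)
  div <- matrix(0, nr, nc)
  if (nc > 1L) {
    div[, 1L] <- -dx[, 1L]
    if (nc > 2L) {
      div[, 2L:(nc - 1L)] <- dx[, 1L:(nc - 2L), drop = FALSE] - dx[, 2L:(nc - 1L), drop = FALSE]
    }
    div[, nc] <- dx[, nc - 1L]
  }
  if (nr > 1L) {
    div[1L, ] <- div[1L, ] - dy[1L, ]
    if (nr > 2L) {
      div[2L:(nr - 1L), ] <- div[2L:(nr - 1L), ] +
        dy[1L:(nr - 2L), , drop = FALSE] - dy[2L:(nr - 1L), , drop = FALSE]
    }
    div[nr, ] <- div[nr, ] + dy[nr - 1L, ]
  }
  -div
}

#' Soft thresholding (proximal operator of the L1 norm)
#'
#' Elementwise `sign(v) * max(|v| - t, 0)`, the exact proximal operator of
#' `t * ||.||_1`.
#'
#' @param v Numeric vector/matrix.
#' @param t Nonnegative threshold.
#' @return Object of the same shape as `v`.
#' @export
soft_threshold <- function(v, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("threshold t must be a nonnegative scalar")
  }
  sign(v) * pmax(abs(v) - t, 0)
}

#' Parameters for the TV proximal solver
#'
#' @param weight Nonnegative prox scale (the TV weight).
#' @param n_inner Inner (dual) iteration count, >= 1.
#' @param tol Relative-change stopping tolerance for the dual iterates;
#'   0 disables early stopping.
#' @return A `tv_params` list.
#' @export
tv_params <- function(weight, n_inner = 20L, tol = 0) {
  if (weight < 0) stop("weight must be >= 0")
  if (n_inner < 1L) stop("n_inner must be >= 1")
  structure(list(weight = as.numeric(weight), n_inner = as.integer(n_inner),
                 tol = as.numeric(tol)), class = "tv_params")
}

#' Proximal operator of the total variation
#'
#' Approximately solves the TV denoising problem
#' `argmin_y 0.5 * ||y - img||^2 + weight * TV(y)` by accelerated projected
#' gradient on the dual (Chambolle-type dual field with pointwise L2-ball
#' constraint, fixed step 1/8, FISTA momentum). The gradient/divergence pair
#' used are mutual negative adjoints, and the returned objective never
#' exceeds the objective at the input.
#'
#' @param img Numeric matrix to denoise.
#' @param params A [tv_params()]; `params$weight` of 0 returns `img` unchanged.
#' @return Matrix of the same shape (an [image2d()] if the input was one).
#' @export
prox_tv <- function(img, params) {
  stopifnot(inherits(params, "tv_params"))
  lam <- params$weight
  m <- as.matrix(img)
  if (lam == 0) return(img)
  px <- matrix(0, nrow(m), ncol(m))
  py <- px
  qx <- px; qy <- py         # momentum fields
  tk <- 1
  for (k in seq_len(params$n_inner)) {
    est <- m + lam * image_divergence(qx, qy)
    g <- image_gradient(est)
    px_new <- qx + (1 / (8 * lam)) * g$dx
    py_new <- qy + (1 / (8 * lam)) * g$dy
    mag <- pmax(1, sqrt(px_new^2 + py_new^2))
    px_new <- px_new / mag
    py_new <- py_new / mag
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    mom <- (tk - 1) / t_new
    qx <- px_new + mom * (px_new - px)
    qy <- py_new + mom * (py_new - py)
    if (params$tol > 0) {
      ch <- sqrt(sum((px_new - px)^2 + (py_new - py)^2)) /
        max(sqrt(sum(px_new^2 + py_new^2)), .Machine$double.eps)
      if (ch < params$tol && k > 1L) {
        px <- px_new; py <- py_new
        break
      }
    }
    px <- px_new; py <- py_new
    tk <- t_new
  }
  out <- m + lam * image_divergence(px, py)
  if (inherits(img, "image2d")) image2d(out) else out
}

#' Largest-eigenvalue estimate by the power method
#'
#' Power iteration on a symmetric positive semidefinite linear operator given
#' as a function. The iterate is a fixed-seed unit random vector, so the
#' result is deterministic given `seed`.
#'
#' @param apply_op Function taking and returning a numeric vector (or array)
#'   of shape `domain_shape`; must implement a symmetric PSD operator.
#' @param domain_shape Integer vector, the operand shape.
#' @param n_iter Maximum iterations.
#' @param tol Relative-change stopping tolerance on the eigenvalue estimate.
#' @param seed Integer seed for the start vector.
#' @return Nonnegative scalar estimate of the largest eigenvalue; 0 for the
#'   zero operator.
#' @export
power_method <- function(apply_op, domain_shape, n_iter = 100L, tol = 1e-6,
                         seed = 1L) {
  n <- prod(domain_shape)
  v <- withr::with_seed(as.integer(seed), stats::rnorm(n))
  v <- v / sqrt(sum(v^2))
  dim_shape <- if (length(domain_shape) > 1L) domain_shape else NULL
  lam <- 0
  for (k in seq_len(n_iter)) {
    x <- v
    if (!is.null(dim_shape)) dim(x) <- dim_shape
    w <- as.numeric(apply_op(x))
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    lam_new <- sum(v * w)   # Rayleigh quotient (v is unit)
    v <- w / nw
    if (k > 1L && abs(lam_new - lam) <= tol * abs(lam_new)) {
      lam <- lam_new
      break
    }
    lam <- lam_new
  }
  max(lam, 0)
}
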
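#' Ring vector replication and its adjoint
#'
#' A ring vector `u` holds one additive offset per detector bin, constant
#' along the projection angle. `ring_replicate` turns it into a full
#' sinogram-shaped field (every angle row equals `u`); `ring_adjoint` is the
#' exact adjoint, the column-wise sum over angles.
#'
#' @param u Numeric vector of length `n_bins`.
#' @param n_angles Number of angle rows.
#' @return `ring_replicate`: an `n_angles x n_bins` matrix; `ring_adjoint`:
#'   a length-`n_bins` vector.
#' @export
ring_replicate <- function(u, n_angles) {
  matrix(u, nrow = n_angles, ncol = length(u), byrow = TRUE)
}

#' @rdname ring_replicate
#' @param field An `n_angles x n_bins` matrix.
#' @export
ring_adjoint <- function(field) {
  colSums(field)
}

#' Solver configuration for the joint slice/rings reconstruction
#'
#' @param beta Nonnegative weight of the spatial regularizer (TV of the
#'   slice, or L1 sparsity of the patch coefficients for the dictionary
#'   solver).
#' @param beta_rings Nonnegative L1 weight on the ring vector `u`. Larger
#'   values force `u` toward zero; `correct_rings = FALSE` freezes `u` at 0.
#' @param n_iter Number of outer FISTA iterations (fixed-count stopping).
#' @param precondition Apply the ramp-filter preconditioner to the residual
#'   in the fidelity term (default `TRUE`). With preconditioning the first
#'   gradient step from zero is proportional to filtered back-projection.
#' @param inner_tv A [tv_params()] giving the inner iteration count and
#'   tolerance of the TV proximal subproblem; its `weight` field is ignored
#'   (the prox scale is `beta / L` at every outer iteration).
#' @param lipschitz_iters Power-method iteration cap for the step-size
#'   (Lipschitz) estimate.
#' @param seed Integer seed for the power-method start vector.
#' @param correct_rings Estimate the ring vector (default `TRUE`). When
#'   `FALSE`, `u` is frozen at zero and `beta_rings` is unused; everything
#'   else, including the step size, is computed identically.
#' @param restart Restart the FISTA momentum when the objective increases
#'   (default `FALSE`).
#' @param warm_start `"zero"` (default) or `"fbp"` to start from the filtered
#'   back-projection of the data.
#' @param n Reconstruction side length; defaults to the bin count.
#' @param rho Nonnegative weight of the patch-overlap coherence penalty
#'   (dictionary solver only).
#' @return A `solver_config` list.
#' @export
solver_config <- function(beta = 0.1, beta_rings = 0.1, n_iter = 100L,
                          precondition = TRUE, inner_tv = tv_params(1, 20L),
                          lipschitz_iters = 100L, seed = 1L,
                          correct_rings = TRUE, restart = FALSE,
                          warm_start = c("zero", "fbp"), n = NULL,
                          rho = 1) {
  if (beta < 0 || beta_rings < 0) stop("beta and beta_rings must be >= 0")
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (rho < 0) stop("rho must be >= 0")
  stopifnot(inherits(inner_tv, "tv_params"))
  structure(list(beta = as.numeric(beta), beta_rings = as.numeric(beta_rings),
                 n_iter = as.integer(n_iter),
                 precondition = isTRUE(precondition), inner_tv = inner_tv,
                 lipschitz_iters = as.integer(lipschitz_iters),
                 seed = as.integer(seed), correct_rings = isTRUE(correct_rings),
                 restart = isTRUE(restart),
                 warm_start = match.arg(warm_start),
                 n = if (is.null(n)) NULL else as.integer(n),
                 rho = as.numeric(rho)),
            class = "solver_config")
}

recon_n <- function(cfg, geom) if (is.null(cfg$n)) geom$n_bins else cfg$n

# apply the (optional) ramp preconditioner M to a residual field
precond_apply <- function(r, precondition) {
  if (precondition) ramp_filter_rows(r) else r
}

#' Gradient of the (optionally preconditioned) fidelity term
#'
#' The fidelity is `0.5 * <r, M r>` with residual `Px + Ru - d` and
#' `M` the ramp-filter preconditioner (the identity when `precondition` is
#' `FALSE`). Its gradient is `(P^T M r, R^T M r)`: a filtered back-projection
#' of the residual for the image block, and the per-bin sum over angles of
#' the filtered residual for the ring block.
#'
#' @param x Square image matrix (current slice estimate).
#' @param u Ring vector of length `n_bins`.
#' @param d A [sinogram()] of acquired data.
#' @param precondition Apply the ramp filter to the residual.
#' @return A list with elements `image` (matrix, same size as `x`) and
#'   `rings` (vector, same length as `u`).
#' @export
fidelity_grad <- function(x, u, d, precondition = TRUE) {
  g <- sino_geometry(d)
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) stop("x must be square")
  if (length(u) != g$n_bins) stop("u must have one entry per detector bin")
  r <- joseph_project_cpp(x, g$angles_rad, g$n_bins, g$rotation_center) +
    ring_replicate(u, length(g$angles_rad)) - unclass_matrix(d)
  mr <- precond_apply(r, precondition)
  list(image = joseph_backproject_cpp(mr, g$angles_rad, nrow(x),
                                      g$rotation_center),
       rings = ring_adjoint(mr))
}

#' Step-size (Lipschitz) estimate for the augmented fidelity
#'
#' Runs the power method on the augmented normal operator
#' `(x, u) -> (P^T M (P x + R u), R^T M (P x + R u))`, whose largest
#' eigenvalue is the Lipschitz constant of the fidelity gradient. The result
#' depends only on the geometry and the preconditioning flag, never on the
#' data, and is deterministic given `cfg$seed`.
#'
#' @param geom A [projection_geometry()].
#' @param precondition Include the ramp-filter preconditioner.
#' @param cfg A [solver_config()] (supplies image size, iteration cap, seed).
#' @param tol Power-method relative-change stopping tolerance.
#' @return Nonnegative scalar.
#' @export
estimate_lipschitz <- function(geom, precondition = TRUE,
                               cfg = solver_config(), tol = 1e-6) {
  n <- recon_n(cfg, geom)
  na <- length(geom$angles_rad)
  nb <- geom$n_bins
  key <- paste(n, nb, geom$rotation_center, precondition,
               cfg$lipschitz_iters, cfg$seed, tol,
               paste(format(geom$angles_rad, digits = 17), collapse = ","),
               sep = "|")
  cached <- .lipschitz_cache[[key]]
  if (!is.null(cached)) return(cached)
  apply_op <- function(v) {
    x <- matrix(v[seq_len(n * n)], n, n)
    u <- v[n * n + seq_len(nb)]
    r <- joseph_project_cpp(x, geom$angles_rad, nb, geom$rotation_center) +
      ring_replicate(u, na)
    mr <- precond_apply(r, precondition)
    c(as.numeric(joseph_backproject_cpp(mr, geom$angles_rad, n,
                                        geom$rotation_center)),
      ring_adjoint(mr))
  }
  L <- power_method(apply_op, n * n + nb, n_iter = cfg$lipschitz_iters,
                    tol = tol, seed = cfg$seed)
  .lipschitz_cache[[key]] <- L
  L
}

# session cache: the step size depends only on geometry and flags, and the
# solvers are often run several times on the same acquisition setup
.lipschitz_cache <- new.env(parent = emptyenv())

#' Objective of the TV + rings reconstruction problem
#'
#' `0.5 * <r, M r> + beta * TV(x) + beta_rings * ||u||_1`, where the
#' residual is `Px + Ru - d` and `M` is the ramp preconditioner when
#' `cfg$precondition` is `TRUE`, else the identity.
#'
#' @inheritParams fidelity_grad
#' @param cfg A [solver_config()].
#' @return A scalar. Use [energy_terms_tv()] for the individual terms.
#' @export
energy_tv <- function(x, u, d, cfg) {
  sum(unlist(energy_terms_tv(x, u, d, cfg)))
}

#' @rdname energy_tv
#' @export
energy_terms_tv <- function(x, u, d, cfg) {
  g <- sino_geometry(d)
  r <- joseph_project_cpp(as.matrix(x), g$angles_rad, g$n_bins,
                          g$rotation_center) +
    ring_replicate(u, length(g$angles_rad)) - unclass_matrix(d)
  list(fidelity = 0.5 * sum(r * precond_apply(r, cfg$precondition)),
       regularization = cfg$beta * tv_norm(x),
       ring_l1 = cfg$beta_rings * sum(abs(u)))
}

new_recon_result <- function(x, u, d, trace, cfg, lipschitz, algorithm) {
  g <- sino_geometry(d)
  corrected <- sinogram(unclass_matrix(d) -
                          ring_replicate(u, length(g$angles_rad)), g)
  structure(list(x = image2d(x), u = u, energy_trace = trace$total,
                 energy_components = trace,
                 corrected_sinogram = corrected, lipschitz = lipschitz,
                 config = cfg, algorithm = algorithm),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("%s reconstruction: %d x %d slice, %d iterations\n",
              x$algorithm, nrow(x$x), ncol(x$x), length(x$energy_trace)))
  cat(sprintf("  energy %.6g -> %.6g; ring vector: %d nonzero of %d bins\n",
              x$energy_trace[1], x$energy_trace[length(x$energy_trace)],
              sum(x$u != 0), length(x$u)))
  invisible(x)
}

#' Joint TV reconstruction with ring correction
#'
#' Minimizes `0.5 * <C r, C r> + beta * TV(x) + beta_rings * ||u||_1` over
#' the slice `x` and the ring vector `u`, with residual `Px + Ru - d`, where
#' `C^T C` is the ramp-filter preconditioner (identity when preconditioning
#' is off). The solver is FISTA on the augmented variable `(x, u)`: one
#' gradient step on the fidelity with step `1/L` (`L` from
#' [estimate_lipschitz()]), then — because the squared norm is separable —
#' a blockwise proximal step: [prox_tv()] with scale `beta/L` on the image
#' block and [soft_threshold()] with `beta_rings/L` on the ring block,
#' followed by the standard FISTA momentum update.
#'
#' @param d A [sinogram()] of acquired data (finite values).
#' @param cfg A [solver_config()].
#' @return A `recon_result` with fields `x` (the slice), `u` (the ring
#'   vector), `energy_trace` (objective per iteration), `energy_components`
#'   (data frame with fidelity / regularization / ring_l1 / total columns),
#'   `corrected_sinogram` (`d` minus the replicated ring vector),
#'   `lipschitz`, `config`.
#' @export
reconstruct_tv_rings <- function(d, cfg = solver_config()) {
  if (!inherits(d, "sinogram")) stop("d must be a sinogram")
  if (!all(is.finite(d))) stop("sinogram must be finite")
  g <- sino_geometry(d)
  n <- recon_n(cfg, g)
  na <- length(g$angles_rad)
  L <- estimate_lipschitz(g, cfg$precondition, cfg)
  if (L <= 0) stop("degenerate geometry: zero Lipschitz constant")
  dmat <- unclass_matrix(d)

  x <- matrix(0, n, n)
  if (cfg$warm_start == "fbp") x <- unclass_matrix(fbp(d, n))
  u <- numeric(g$n_bins)
  yx <- x; yu <- u
  px_cur <- joseph_project_cpp(x, g$angles_rad, g$n_bins, g$rotation_center)
  py <- px_cur                      # P applied to the momentum iterate
  tk <- 1
  tv_scale <- function(L) tv_params(cfg$beta / L, cfg$inner_tv$n_inner,
                                    cfg$inner_tv$tol)
  trace <- data.frame(iteration = seq_len(cfg$n_iter), fidelity = NA_real_,
                      regularization = NA_real_, ring_l1 = NA_real_,
                      total = NA_real_)
  best <- Inf

  for (k in seq_len(cfg$n_iter)) {
    r <- py + ring_replicate(yu, na) - dmat
    mr <- precond_apply(r, cfg$precondition)
    gx <- joseph_backproject_cpp(mr, g$angles_rad, n, g$rotation_center)
    zx <- yx - gx / L
    x_new <- if (cfg$beta > 0) as.matrix(prox_tv(zx, tv_scale(L))) else zx
    u_new <- if (cfg$correct_rings) {
      soft_threshold(yu - ring_adjoint(mr) / L, cfg$beta_rings / L)
    } else u
    px_new <- joseph_project_cpp(x_new, g$angles_rad, g$n_bins,
                                 g$rotation_center)

    r_new <- px_new + ring_replicate(u_new, na) - dmat
    fid <- 0.5 * sum(r_new * precond_apply(r_new, cfg$precondition))
    reg <- cfg$beta * tv_norm(x_new)
    rl1 <- cfg$beta_rings * sum(abs(u_new))
    total <- fid + reg + rl1
    trace[k, 2:5] <- c(fid, reg, rl1, total)

    if (cfg$restart && total > best) tk <- 1
    best <- min(best, total)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    mom <- (tk - 1) / t_new
    yx <- x_new + mom * (x_new - x)
    yu <- u_new + mom * (u_new - u)
    py <- (1 + mom) * px_new - mom * px_cur
    x <- x_new; u <- u_new; px_cur <- px_new; tk <- t_new
  }
  new_recon_result(x, u, d, trace, cfg, L, "TV")
}

#' Objective of the dictionary-learning + rings reconstruction problem
#'
#' `0.5 * <r, M r> + rho * h(W) + beta * ||W||_1 + beta_rings * ||u||_1`,
#' where the slice is synthesized from the patch coefficients (the
#' residual is `P x(W) + R u - d`) and `h` is the overlap-coherence penalty.
#'
#' @param W Patch coefficient matrix.
#' @param u Ring vector.
#' @param d A [sinogram()].
#' @param dict A [patch_dictionary()].
#' @param grid A [patch_grid()].
#' @param cfg A [solver_config()].
#' @return A scalar.
#' @export
energy_dl <- function(W, u, d, dict, grid, cfg) {
  g <- sino_geometry(d)
  x <- dict_synth_core(as.matrix(W), dict, grid)
  r <- joseph_project_cpp(x, g$angles_rad, g$n_bins, g$rotation_center) +
    ring_replicate(u, length(g$angles_rad)) - unclass_matrix(d)
  0.5 * sum(r * precond_apply(r, cfg$precondition)) +
    cfg$rho * overlap_coherence(W, dict, grid)$value +
    cfg$beta * sum(abs(W)) + cfg$beta_rings * sum(abs(u))
}

#' Joint dictionary-learning reconstruction with ring correction
#'
#' Reconstructs the slice as a sparse combination of overlapping dictionary
#' patches while estimating the angle-constant ring vector. A single FISTA
#' loop over `(W, u)` suffices: the smooth part is the (optionally
#' ramp-preconditioned) fidelity of the synthesized slice plus the quadratic
#' overlap-coherence term `rho * h(W)`; the non-smooth part is
#' `beta * ||W||_1 + beta_rings * ||u||_1`, whose proximal operator is
#' blockwise soft thresholding.
#'
#' @param d A [sinogram()] of acquired data.
#' @param dict A [patch_dictionary()] whose grid (patch size and stride) must
#'   tile the reconstruction square exactly.
#' @param cfg A [solver_config()]; `cfg$beta` weights the coefficient
#'   sparsity, `cfg$rho` the overlap coherence.
#' @param stride Patch stride; default half the patch size (50% overlap).
#' @return A `recon_result` (see [reconstruct_tv_rings()]) with an extra
#'   field `W`, the patch coefficients.
#' @export
reconstruct_dl_rings <- function(d, dict, cfg = solver_config(),
                                 stride = dict$patch_size %/% 2L) {
  if (!inherits(d, "sinogram")) stop("d must be a sinogram")
  if (!all(is.finite(d))) stop("sinogram must be finite")
  g <- sino_geometry(d)
  n <- recon_n(cfg, g)
  na <- length(g$angles_rad)
  grid <- patch_grid(n, dict$patch_size, stride)
  np <- nrow(grid$origins); nk <- nrow(dict$atoms); nb <- g$n_bins
  dmat <- unclass_matrix(d)

  smooth_grad <- function(W, u) {
    x <- dict_synth_core(W, dict, grid)
    r <- joseph_project_cpp(x, g$angles_rad, nb, g$rotation_center) +
      ring_replicate(u, na) - dmat
    mr <- precond_apply(r, cfg$precondition)
    bp <- joseph_backproject_cpp(mr, g$angles_rad, n, g$rotation_center)
    gW <- patch_analyze(bp, dict, grid)
    if (cfg$rho > 0) gW <- gW + cfg$rho * overlap_coherence(W, dict, grid)$grad
    list(W = gW, u = ring_adjoint(mr))
  }

  # Lipschitz of the smooth part: power method on its (linear) Hessian map
  hess_apply <- function(v) {
    W <- matrix(v[seq_len(np * nk)], np, nk)
    u <- v[np * nk + seq_len(nb)]
    x <- dict_synth_core(W, dict, grid)
    r <- joseph_project_cpp(x, g$angles_rad, nb, g$rotation_center) +
      ring_replicate(u, na)
    mr <- precond_apply(r, cfg$precondition)
    bp <- joseph_backproject_cpp(mr, g$angles_rad, n, g$rotation_center)
    gW <- patch_analyze(bp, dict, grid)
    if (cfg$rho > 0) gW <- gW + cfg$rho * overlap_coherence(W, dict, grid)$grad
    c(as.numeric(gW), ring_adjoint(mr))
  }
  L <- power_method(hess_apply, np * nk + nb, n_iter = cfg$lipschitz_iters,
                    tol = 1e-6, seed = cfg$seed)
  if (L <= 0) stop("degenerate geometry: zero Lipschitz constant")

  W <- matrix(0, np, nk); u <- numeric(nb)
  yW <- W; yu <- u; tk <- 1
  trace <- data.frame(iteration = seq_len(cfg$n_iter), fidelity = NA_real_,
                      regularization = NA_real_, ring_l1 = NA_real_,
                      total = NA_real_)
  best <- Inf

  for (k in seq_len(cfg$n_iter)) {
    gr <- smooth_grad(yW, yu)
    W_new <- soft_threshold(yW - gr$W / L, cfg$beta / L)
    u_new <- if (cfg$correct_rings) {
      soft_threshold(yu - gr$u / L, cfg$beta_rings / L)
    } else u

    x_new <- dict_synth_core(W_new, dict, grid)
    r_new <- joseph_project_cpp(x_new, g$angles_rad, nb, g$rotation_center) +
      ring_replicate(u_new, na) - dmat
    fid <- 0.5 * sum(r_new * precond_apply(r_new, cfg$precondition))
    reg <- cfg$rho * overlap_coherence(W_new, dict, grid)$value +
      cfg$beta * sum(abs(W_new))
    rl1 <- cfg$beta_rings * sum(abs(u_new))
    total <- fid + reg + rl1
    trace[k, 2:5] <- c(fid, reg, rl1, total)

    if (cfg$restart && total > best) tk <- 1
    best <- min(best, total)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    mom <- (tk - 1) / t_new
    yW <- W_new + mom * (W_new - W)
    yu <- u_new + mom * (u_new - u)
    W <- W_new; u <- u_new; tk <- t_new
  }
  out <- new_recon_result(dict_synth_core(W, dict, grid), u, d, trace, cfg, L,
                          "dictionary")
  out$W <- W
  out
}
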
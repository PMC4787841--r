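#' Patch dictionary
#'
#' A set of `n_atoms` square-patch atoms of side `patch_size`, stored as the
#' rows of an `n_atoms x patch_size^2` matrix (patches are vectorized
#' column-major). Atoms are normalized to unit L2 norm on construction.
#'
#' @param atoms `n_atoms x (patch_size^2)` numeric matrix.
#' @param patch_size Patch side length `w`.
#' @return A `patch_dictionary`.
#' @export
patch_dictionary <- function(atoms, patch_size) {
  atoms <- as.matrix(atoms)
  patch_size <- as.integer(patch_size)
  if (ncol(atoms) != patch_size^2) stop("atoms must have patch_size^2 columns")
  if (nrow(atoms) < 1L) stop("need at least one atom")
  nrm <- sqrt(rowSums(atoms^2))
  if (any(nrm == 0)) stop("atoms must be nonzero")
  structure(list(atoms = atoms / nrm, patch_size = patch_size),
            class = "patch_dictionary")
}

#' @export
print.patch_dictionary <- function(x, ...) {
  cat(sprintf("patch dictionary: %d atoms of %d x %d pixels\n",
              nrow(x$atoms), x$patch_size, x$patch_size))
  invisible(x)
}

#' Regular patch grid over a square image
#'
#' Top-left corners of `w x w` patches at the given stride; the grid must
#' tile the image exactly (`(n - w) %% stride == 0`).
#'
#' @param n Image side length.
#' @param w Patch side length.
#' @param stride Step between patch origins; `stride < w` gives overlap.
#' @return A `patch_grid` list with `origins` (2-column matrix of 1-based
#'   row/col corners), `n`, `w`, `stride`.
#' @export
patch_grid <- function(n, w, stride = w %/% 2L) {
  n <- as.integer(n); w <- as.integer(w); stride <- as.integer(stride)
  if (stride < 1L || w < 1L || w > n) stop("invalid patch grid")
  if ((n - w) %% stride != 0L) {
    stop("patch grid must cover the image exactly: (n - w) %% stride == 0")
  }
  pos <- seq(1L, n - w + 1L, by = stride)
  origins <- as.matrix(expand.grid(row = pos, col = pos))
  structure(list(origins = origins, n = n, w = w, stride = stride),
            class = "patch_grid")
}

# linear indices into an n x n image for patch p of the grid (column-major)
patch_indices <- function(grid, p) {
  o <- grid$origins[p, ]
  rows <- o[["row"]]:(o[["row"]] + grid$w - 1L)
  cols <- o[["col"]]:(o[["col"]] + grid$w - 1L)
  as.vector(outer(rows, (cols - 1L) * grid$n, "+"))
}

# n_patches x w^2 index matrix (each row: linear pixel indices of one patch)
patch_index_matrix <- function(grid) {
  t(vapply(seq_len(nrow(grid$origins)), function(p) patch_indices(grid, p),
           integer(grid$w^2)))
}

# per-pixel coverage count of the grid
patch_coverage <- function(grid) {
  z <- numeric(grid$n^2)
  idx <- patch_index_matrix(grid)
  for (p in seq_len(nrow(idx))) z[idx[p, ]] <- z[idx[p, ]] + 1
  matrix(z, grid$n, grid$n)
}

#' Synthesize an image from patch coefficients
#'
#' Each patch is reconstructed as its coefficient row times the atom matrix;
#' the image pixel value is the uniform average of all overlapping patch
#' reconstructions covering it (overlap-average window). The map is linear
#' in `W`; [patch_analyze()] is its exact adjoint.
#'
#' @param W `n_patches x n_atoms` coefficient matrix.
#' @param dict A [patch_dictionary()].
#' @param grid A [patch_grid()] consistent with `dict$patch_size`.
#' @return An [image2d()] of side `grid$n`.
#' @export
patch_synthesize <- function(W, dict, grid) {
  check_patch_setup(W, dict, grid)
  v <- dict_synth_core(as.matrix(W), dict, grid)
  image2d(v)
}

dict_synth_core <- function(W, dict, grid) {
  idx <- patch_index_matrix(grid)
  recon <- W %*% dict$atoms                 # n_patches x w^2
  acc <- numeric(grid$n^2)
  for (p in seq_len(nrow(idx))) acc[idx[p, ]] <- acc[idx[p, ]] + recon[p, ]
  matrix(acc, grid$n, grid$n) / patch_coverage(grid)
}

#' Adjoint of [patch_synthesize()]
#'
#' Satisfies `sum(patch_synthesize(W) * y) == sum(W * patch_analyze(y))`.
#'
#' @param img Numeric matrix of side `grid$n`.
#' @inheritParams patch_synthesize
#' @return An `n_patches x n_atoms` matrix.
#' @export
patch_analyze <- function(img, dict, grid) {
  img <- as.matrix(img)
  if (nrow(img) != grid$n || ncol(img) != grid$n) stop("image/grid mismatch")
  scaled <- img / patch_coverage(grid)
  extract_patches(scaled, grid) %*% t(dict$atoms)
}

# n_patches x w^2 matrix of raw patch pixel values
extract_patches <- function(img, grid) {
  idx <- patch_index_matrix(grid)
  v <- as.numeric(img)
  matrix(v[t(idx)], nrow = nrow(idx), byrow = TRUE)
}

check_patch_setup <- function(W, dict, grid) {
  if (!inherits(dict, "patch_dictionary")) stop("dict must be a patch_dictionary")
  if (!inherits(grid, "patch_grid")) stop("grid must be a patch_grid")
  if (grid$w != dict$patch_size) stop("grid and dictionary patch sizes differ")
  W <- as.matrix(W)
  if (nrow(W) != nrow(grid$origins) || ncol(W) != nrow(dict$atoms)) {
    stop("W must be n_patches x n_atoms")
  }
  invisible(TRUE)
}

#' Overlap coherence penalty and its gradient
#'
#' Quadratic penalty promoting agreement between overlapping patch
#' reconstructions: `h(W) = sum over pixels of sum over covering patches of
#' (v_p(pixel) - mean(pixel))^2`, where `v_p` is the reconstruction of patch
#' `p` and the mean is over all patches covering the pixel. For a pixel
#' shared by two patches with values `a`, `b` this contributes
#' `(a - b)^2 / 2`. Smooth in `W`; the analytic gradient is returned. A
#' non-overlapping grid gives 0.
#'
#' @inheritParams patch_synthesize
#' @return List with `value` (nonnegative scalar) and `grad`
#'   (`n_patches x n_atoms` matrix).
#' @export
overlap_coherence <- function(W, dict, grid) {
  check_patch_setup(W, dict, grid)
  W <- as.matrix(W)
  if (grid$stride >= grid$w) {
    return(list(value = 0, grad = matrix(0, nrow(W), ncol(W))))
  }
  idx <- patch_index_matrix(grid)
  recon <- W %*% dict$atoms
  xbar <- as.numeric(dict_synth_core(W, dict, grid))
  # per-patch deviation from the overlap average at each covered pixel
  dev <- recon - matrix(xbar[t(idx)], nrow = nrow(idx), byrow = TRUE)
  list(value = sum(dev^2), grad = 2 * dev %*% t(dict$atoms))
}

#' Orthogonal matching pursuit sparse coding
#'
#' Greedy sparse coding of each patch against the dictionary: repeatedly
#' select the atom most correlated with the residual and re-solve the least
#' squares fit on the selected support, up to `sparsity` atoms per patch.
#'
#' @param patches `n_patches x w^2` matrix of signals (rows).
#' @param dict A [patch_dictionary()].
#' @param sparsity Maximum number of atoms per patch (>= 1).
#' @param tol Stop early when the residual norm falls below `tol`.
#' @return Sparse coefficient matrix, `n_patches x n_atoms`.
#' @export
omp_code <- function(patches, dict, sparsity, tol = 1e-10) {
  patches <- as.matrix(patches)
  A <- t(dict$atoms)                        # w^2 x n_atoms, unit columns
  K <- ncol(A)
  W <- matrix(0, nrow(patches), K)
  for (i in seq_len(nrow(patches))) {
    y <- patches[i, ]
    res <- y
    sel <- integer(0)
    for (s in seq_len(sparsity)) {
      if (sqrt(sum(res^2)) < tol) break
      cor_ <- abs(crossprod(A, res))
      cor_[sel] <- -Inf
      k <- which.max(cor_)
      sel <- c(sel, k)
      coef <- qr.solve(A[, sel, drop = FALSE], y)
      res <- y - A[, sel, drop = FALSE] %*% coef
    }
    if (length(sel)) W[i, sel] <- coef
  }
  W
}

#' Learn a patch dictionary by K-SVD
#'
#' Alternates orthogonal matching pursuit sparse coding with sequential
#' rank-one (SVD) atom updates on the patches that use each atom. Atoms are
#' kept unit-normalized; unused atoms are re-seeded to the currently
#' worst-represented patch. Deterministic given `seed`.
#'
#' @param training_images List of numeric matrices (or a single matrix) to
#'   draw training patches from.
#' @param n_atoms Number of atoms to learn.
#' @param w Patch side length.
#' @param sparsity_target Atoms per patch used during coding.
#' @param n_epochs Number of coding/update sweeps.
#' @param seed Integer seed (initial atoms are random training patches).
#' @param stride Patch sampling stride in the training images (default `w`,
#'   non-overlapping).
#' @return A [patch_dictionary()] with attribute `train_error`: the root
#'   mean squared patch reconstruction error after each epoch.
#' @export
learn_dictionary <- function(training_images, n_atoms, w, sparsity_target = 3L,
                             n_epochs = 10L, seed = 1L, stride = w) {
  if (is.matrix(training_images)) training_images <- list(training_images)
  patches <- do.call(rbind, lapply(training_images, function(im) {
    im <- as.matrix(im)
    pos <- seq(1L, nrow(im) - w + 1L, by = stride)
    do.call(rbind, lapply(pos, function(r) {
      t(vapply(pos, function(c0) as.numeric(im[r:(r + w - 1L),
                                               c0:(c0 + w - 1L)]),
               numeric(w * w)))
    }))
  }))
  if (nrow(patches) < 10L * n_atoms) {
    stop("need at least 10 training patches per atom")
  }
  if (stats::sd(patches) == 0) stop("training data is constant (degenerate)")

  X <- t(patches)                           # w^2 x n_patches
  np <- ncol(X)
  nz <- which(colSums(X^2) > 0)
  init <- withr::with_seed(as.integer(seed),
                           sample(nz, n_atoms, replace = length(nz) < n_atoms))
  D <- X[, init, drop = FALSE]
  D <- sweep(D, 2L, sqrt(colSums(D^2)), "/")
  err <- numeric(n_epochs)

  for (ep in seq_len(n_epochs)) {
    dict <- patch_dictionary(t(D), w)
    W <- omp_code(t(X), dict, sparsity_target)       # np x n_atoms
    Wt <- t(W)                                       # n_atoms x np
    for (k in seq_len(n_atoms)) {
      users <- which(Wt[k, ] != 0)
      if (!length(users)) {
        # re-seed a dead atom to the worst-represented patch
        resid_all <- X - D %*% Wt
        worst <- which.max(colSums(resid_all^2))
        D[, k] <- X[, worst] / sqrt(sum(X[, worst]^2))
        next
      }
      Ek <- X[, users, drop = FALSE] -
        D[, -k, drop = FALSE] %*% Wt[-k, users, drop = FALSE]
      sv <- svd(Ek, nu = 1, nv = 1)
      D[, k] <- sv$u[, 1]
      Wt[k, users] <- sv$d[1] * sv$v[, 1]
    }
    err[ep] <- sqrt(mean((X - D %*% Wt)^2))
  }
  out <- patch_dictionary(t(D), w)
  attr(out, "train_error") <- err
  out
}

#' Save / load a dictionary as a flat text array with a structured sidecar
#'
#' The atom matrix is written one value per line (row-major over atoms); a
#' YAML sidecar `<file>.yaml` records `n_atoms` and `patch_size`.
#'
#' @param dict A [patch_dictionary()].
#' @param file Path of the flat value file.
#' @return `write_dictionary`: `file`, invisibly. `read_dictionary`: the
#'   dictionary.
#' @export
write_dictionary <- function(dict, file) {
  writeLines(formatC(as.numeric(t(dict$atoms)), format = "g", digits = 17),
             file)
  yaml::write_yaml(list(n_atoms = nrow(dict$atoms),
                        patch_size = dict$patch_size),
                   paste0(file, ".yaml"))
  invisible(file)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(file) {
  meta <- yaml::read_yaml(paste0(file, ".yaml"))
  v <- as.numeric(readLines(file))
  patch_dictionary(matrix(v, nrow = meta$n_atoms, byrow = TRUE),
                   meta$patch_size)
}
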
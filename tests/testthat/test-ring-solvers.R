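toy_setup <- function(n = 24, na = 30, seed = 5) {
  set.seed(seed)
  g <- half_turn_geometry(na, n)
  list(g = g,
       x = matrix(rnorm(n * n), n),
       u = rnorm(n),
       d = sinogram(matrix(rnorm(na * n), na), g))
}

test_that("ring replication and its adjoint form an exact adjoint pair", {
  set.seed(1)
  u <- rnorm(16); y <- matrix(rnorm(10 * 16), 10)
  expect_equal(sum(ring_replicate(u, 10) * y), sum(u * ring_adjoint(y)))
  expect_identical(dim(ring_replicate(u, 10)), c(10L, 16L))
  expect_true(all(ring_replicate(u, 10)[3, ] == u))
})

test_that("fidelity gradient vanishes on consistent data", {
  ts <- toy_setup()
  d <- project(image2d(ts$x), ts$g)
  d2 <- sinogram(unclass(d) + ring_replicate(ts$u, 30), ts$g)
  for (pc in c(FALSE, TRUE)) {
    gr <- fidelity_grad(ts$x, ts$u, d2, pc)
    expect_lt(max(abs(gr$image)), 1e-9)
    expect_lt(max(abs(gr$rings)), 1e-9)
  }
})

test_that("fidelity gradient matches finite differences", {
  ts <- toy_setup()
  n <- 24; na <- 30
  energy <- function(x, u, pc) {
    r <- project(image2d(x), ts$g) + ring_replicate(u, na) - unclass(ts$d)
    0.5 * sum(r * ringtomo:::precond_apply(unclass(r), pc))
  }
  set.seed(6)
  dx <- matrix(rnorm(n * n), n); du <- rnorm(n); eps <- 1e-6
  for (pc in c(FALSE, TRUE)) {
    gr <- fidelity_grad(ts$x, ts$u, ts$d, pc)
    fd <- (energy(ts$x + eps * dx, ts$u + eps * du, pc) -
             energy(ts$x - eps * dx, ts$u - eps * du, pc)) / (2 * eps)
    an <- sum(gr$image * dx) + sum(gr$rings * du)
    expect_lt(abs(fd - an) / abs(an), 1e-4)
  }
})

test_that("with zero estimates the image gradient is minus the FBP direction", {
  sc <- case1_small()
  gr <- fidelity_grad(matrix(0, 64, 64), numeric(64), sc$corrupt, TRUE)
  f <- fbp(sc$corrupt)
  cs <- sum(-gr$image * f) / sqrt(sum(gr$image^2) * sum(f^2))
  expect_gt(cs, 0.9999)
  # ring gradient is minus the per-bin sum of the filtered data
  mr <- ringtomo:::ramp_filter_rows(unclass(sc$corrupt))
  expect_equal(gr$rings, -colSums(mr))
})

test_that("the Lipschitz estimate depends on geometry, not data, and both
           preconditioned and plain variants are positive", {
  g <- half_turn_geometry(20, 16)
  cfg <- solver_config(n = 16)
  l_pc <- estimate_lipschitz(g, TRUE, cfg)
  l_raw <- estimate_lipschitz(g, FALSE, cfg)
  expect_gt(l_pc, 0)
  expect_gt(l_raw, 0)
  expect_false(isTRUE(all.equal(l_pc, l_raw)))
  # deterministic given seed
  expect_identical(l_pc, estimate_lipschitz(g, TRUE, solver_config(n = 16)))
})

test_that("augmented Lipschitz matches a densely assembled normal operator", {
  g <- projection_geometry(seq(0, pi, length.out = 7)[1:6], 8)
  cfg <- solver_config(n = 4, lipschitz_iters = 20000L)
  for (pc in c(TRUE, FALSE)) {
    dim_tot <- 16 + 8
    H <- matrix(0, dim_tot, dim_tot)
    for (i in seq_len(dim_tot)) {
      v <- numeric(dim_tot); v[i] <- 1
      x <- matrix(v[1:16], 4, 4); u <- v[17:24]
      r <- project(image2d(x), g) + ring_replicate(u, 6)
      mr <- ringtomo:::precond_apply(unclass(r), pc)
      H[, i] <- c(as.numeric(backproject(sinogram(mr, g), 4)), colSums(mr))
    }
    lam_dense <- max(eigen((H + t(H)) / 2, symmetric = TRUE)$values)
    L <- estimate_lipschitz(g, pc, cfg, tol = 1e-12)
    expect_lt(abs(L - lam_dense) / lam_dense, 1e-4)
  }
})

test_that("the augmented normal operator has the n_angles * I ring block", {
  # without preconditioning, R^T R u = n_angles * u exactly
  g <- half_turn_geometry(13, 8)
  u <- rnorm(8)
  expect_equal(ring_adjoint(ring_replicate(u, 13)), 13 * u)
})

test_that("TV energy matches a term-by-term hand evaluation on a toy case", {
  g <- projection_geometry(c(0, pi / 2), 2)
  x <- matrix(c(1, 2, 3, 4), 2)
  u <- c(0.5, -1)
  d <- sinogram(matrix(c(1, 0, 0, 1), 2), g)
  cfg <- solver_config(beta = 0.7, beta_rings = 0.3, precondition = FALSE)
  r <- unclass(project(image2d(x), g)) + ring_replicate(u, 2) - unclass(d)
  by_hand <- 0.5 * sum(r^2) + 0.7 * tv_norm(x) + 0.3 * (0.5 + 1)
  expect_equal(energy_tv(x, u, d, cfg), by_hand)
  # special cases
  cfg0 <- solver_config(beta = 0, beta_rings = 0, precondition = FALSE)
  expect_equal(energy_tv(matrix(0, 2, 2), c(0, 0), d, cfg0),
               0.5 * sum(unclass(d)^2))
  dc <- project(image2d(x), g)
  cfgb <- solver_config(beta = 0.7, beta_rings = 0.3, precondition = FALSE)
  expect_equal(energy_tv(x, c(0, 0), dc, cfgb), 0.7 * tv_norm(x))
})

test_that("the blockwise prox equals the prox of the separable sum", {
  # prox of beta*TV(x) + beta_r*||u||_1 on the augmented vector splits into
  # the image prox and the ring soft threshold evaluated independently
  set.seed(13)
  zx <- matrix(rnorm(64), 8); zu <- rnorm(12)
  lam_x <- 0.2; lam_u <- 0.45
  joint_obj <- function(x, u) {
    0.5 * (sum((x - zx)^2) + sum((u - zu)^2)) +
      lam_x * tv_norm(x) + lam_u * sum(abs(u))
  }
  bx <- prox_tv(zx, tv_params(lam_x, 400))
  bu <- soft_threshold(zu, lam_u)
  # blockwise answer beats any jointly perturbed candidate
  for (trial in 1:10) {
    px <- bx + 1e-3 * matrix(rnorm(64), 8)
    pu <- bu + 1e-3 * rnorm(12)
    expect_lte(joint_obj(bx, bu), joint_obj(px, pu) + 1e-10)
  }
})

test_that("stripe-free consistent data is reconstructed faithfully", {
  sc <- case1_small()
  res <- reconstruct_tv_rings(sc$clean,
                              solver_config(beta = 0.05, beta_rings = 0.5,
                                            n_iter = 300L))
  expect_gt(psnr(sc$phantom, res$x), 30)
  expect_lt(max(abs(res$u)), 0.05 * max(abs(sc$clean)))
})

test_that("a huge ring penalty freezes u at zero, bitwise equal to the
           u-frozen solver", {
  sc <- case1_small()
  d <- sc$corrupt
  big <- 1e6 * max(abs(d))
  a <- reconstruct_tv_rings(d, solver_config(beta = 0.1, beta_rings = big,
                                             n_iter = 40L))
  b <- reconstruct_tv_rings(d, solver_config(beta = 0.1, beta_rings = big,
                                             n_iter = 40L,
                                             correct_rings = FALSE))
  expect_true(all(a$u == 0))
  expect_identical(unclass(a$x), unclass(b$x))
})

test_that("solver input validation", {
  expect_error(reconstruct_tv_rings(matrix(0, 4, 4)), "sinogram")
  expect_error(solver_config(beta = -1), ">= 0")
  expect_error(solver_config(n_iter = 0), "n_iter")
  ts <- toy_setup()
  expect_error(fidelity_grad(matrix(0, 3, 4), numeric(24), ts$d), "square")
  expect_error(fidelity_grad(matrix(0, 24, 24), numeric(5), ts$d), "bin")
})

test_that("TV solver captures constant stripes in u on the small fixture", {
  sc <- case1_small()
  res <- reconstruct_tv_rings(sc$corrupt,
                              solver_config(beta = 0.05, beta_rings = 0.5,
                                            n_iter = 200L))
  top6 <- sort(order(abs(res$u), decreasing = TRUE)[1:6]) - 1L
  expect_identical(top6, sc$stripe_bins)
  amp <- 0.05 * max(sc$clean)
  expect_lt(max(abs(res$u[sc$stripe_bins + 1] - amp)) / amp, 0.2)
  # the corrected sinogram is the data minus the replicated ring vector
  expect_equal(unclass(res$corrected_sinogram),
               unclass(sc$corrupt) - ring_replicate(res$u, 90))
})

test_that("dictionary solver recovers a synthesized slice and zero data", {
  set.seed(11)
  n <- 64
  grid <- patch_grid(n, 8, 4)
  dict <- patch_dictionary(matrix(rnorm(24 * 64), 24), 8)
  Wt <- matrix(0, nrow(grid$origins), 24)
  for (i in seq_len(nrow(Wt))) Wt[i, sample(24, 2)] <- rnorm(2)
  xt <- patch_synthesize(Wt, dict, grid)
  g <- half_turn_geometry(90, n)
  d <- project(xt, g)
  res <- reconstruct_dl_rings(d, dict,
                              solver_config(beta = 1e-3,
                                            beta_rings = 1e6 * max(abs(d)),
                                            n_iter = 300L, rho = 0))
  expect_gt(psnr(xt, res$x), 30)
  expect_true(all(res$u == 0))
  d0 <- sinogram(matrix(0, 90, n), g)
  r0 <- reconstruct_dl_rings(d0, dict,
                             solver_config(beta = 0.01, beta_rings = 0.1,
                                           n_iter = 5L))
  expect_true(all(r0$x == 0) && all(r0$u == 0))
})

test_that("dictionary solver rejects incompatible patch grids", {
  g <- half_turn_geometry(30, 30)
  d <- sinogram(matrix(0, 30, 30), g)
  dict <- patch_dictionary(matrix(rnorm(4 * 64), 4), 8)
  # (30 - 8) %% 4 != 0: the grid cannot tile the slice
  expect_error(reconstruct_dl_rings(d, dict), "exactly")
})

test_that("dictionary solver captures stripes in u", {
  runs <- dl_small_runs()
  sc <- runs$scenario
  top6 <- sort(order(abs(runs$on$u), decreasing = TRUE)[1:6]) - 1L
  expect_identical(top6, sc$stripe_bins)
  expect_gt(psnr(sc$phantom, runs$on$x), psnr(sc$phantom, runs$off$x))
})
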
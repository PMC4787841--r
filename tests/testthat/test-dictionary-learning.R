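random_dict <- function(n_atoms = 16, w = 8, seed = 9) {
  withr::with_seed(seed, patch_dictionary(matrix(rnorm(n_atoms * w * w),
                                                 n_atoms), w))
}

test_that("dictionary constructor normalizes atoms and validates shapes", {
  set.seed(4)
  expect_equal(unname(rowSums(patch_dictionary(matrix(rnorm(12), 3),
                                               2)$atoms^2)),
               rep(1, 3))
  expect_error(patch_dictionary(matrix(1, 2, 5), 2), "patch_size")
  expect_error(patch_grid(32, 8, 5), "exactly")
  expect_error(patch_grid(8, 9, 1), "invalid")
})

test_that("patch synthesis: zero coefficients and single-atom pasting", {
  dict <- random_dict()
  grid <- patch_grid(32, 8, 4)
  W0 <- matrix(0, nrow(grid$origins), 16)
  expect_true(all(patch_synthesize(W0, dict, grid) == 0))
  # non-overlapping grid: one active patch pastes its atom verbatim
  gridn <- patch_grid(32, 8, 8)
  W1 <- matrix(0, nrow(gridn$origins), 16)
  W1[1, 3] <- 1
  out <- patch_synthesize(W1, dict, gridn)
  expect_equal(as.numeric(out[1:8, 1:8]), dict$atoms[3, ])
  expect_true(all(out[9:32, ] == 0) && all(out[, 9:32] == 0))
})

test_that("patch synthesis and analysis are exact adjoints and linear", {
  set.seed(9)
  dict <- random_dict()
  grid <- patch_grid(32, 8, 4)
  np <- nrow(grid$origins)
  for (trial in 1:5) {
    W <- matrix(rnorm(np * 16), np)
    y <- matrix(rnorm(32 * 32), 32)
    lhs <- sum(as.matrix(patch_synthesize(W, dict, grid)) * y)
    rhs <- sum(W * patch_analyze(y, dict, grid))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  }
  W1 <- matrix(rnorm(np * 16), np); W2 <- matrix(rnorm(np * 16), np)
  expect_lt(rel_err(as.matrix(patch_synthesize(2 * W1 - W2, dict, grid)),
                    2 * as.matrix(patch_synthesize(W1, dict, grid)) -
                      as.matrix(patch_synthesize(W2, dict, grid))), 1e-12)
})

test_that("overlap coherence: zero on agreement, quadratic on disagreement,
           gradient matches finite differences", {
  dict <- random_dict()
  grid <- patch_grid(32, 8, 4)
  np <- nrow(grid$origins)
  # constant atom, equal weights -> all patch reconstructions agree
  dc <- patch_dictionary(matrix(1, 1, 64), 8)
  Wc <- matrix(2.5, np, 1)
  expect_equal(overlap_coherence(Wc, dc, grid)$value, 0)
  # non-overlapping grid returns exactly zero
  gridn <- patch_grid(32, 8, 8)
  Wn <- matrix(rnorm(nrow(gridn$origins) * 16), ncol = 16)
  expect_identical(overlap_coherence(Wn, dict, gridn)$value, 0)
  # two overlapping 1-pixel patches with values a, b -> (a-b)^2 / 2
  d1 <- patch_dictionary(matrix(1, 1, 1), 1)
  g1 <- patch_grid(1, 1, 1)
  expect_equal(overlap_coherence(matrix(3, 1, 1), d1, g1)$value, 0)
  set.seed(10)
  W <- matrix(rnorm(np * 16), np)
  oc <- overlap_coherence(W, dict, grid)
  dW <- matrix(rnorm(np * 16), np); eps <- 1e-6
  fd <- (overlap_coherence(W + eps * dW, dict, grid)$value -
           overlap_coherence(W - eps * dW, dict, grid)$value) / (2 * eps)
  expect_lt(abs(fd - sum(oc$grad * dW)) / abs(fd), 1e-5)
})

test_that("two patches sharing pixels contribute half the squared gap", {
  # 1-atom dictionary of constant patches on a 1-pixel-overlap grid: each
  # shared pixel sees values a and b, contributing (a-b)^2 / 2
  w <- 2
  dc <- patch_dictionary(matrix(1, 1, w * w), w)
  grid <- patch_grid(3, w, 1)   # 2x2 grid of 2x2 patches on a 3x3 image
  W <- matrix(0, 4, 1)
  W[1, 1] <- 1 * 2; W[2, 1] <- 3 * 2  # atoms are normalized to 1/2 per pixel
  a <- 1; b <- 3
  # patches 1 and 2 share 2 pixels; all other patches are zero and share
  # pixels with both -> compare against a direct enumeration
  recon <- (W %*% dc$atoms)
  idx <- ringtomo:::patch_index_matrix(grid)
  vals <- matrix(NA_real_, 9, 4)
  for (p in 1:4) vals[idx[p, ], p] <- recon[p, ]
  hand <- 0
  for (px in 1:9) {
    v <- stats::na.omit(vals[px, ])
    hand <- hand + sum((v - mean(v))^2)
  }
  expect_equal(overlap_coherence(W, dc, grid)$value, hand)
})

test_that("OMP respects the sparsity budget and codes exact data exactly", {
  set.seed(14)
  dict <- random_dict(n_atoms = 12, w = 4)
  X <- matrix(rnorm(40 * 16), 40)
  W <- omp_code(X, dict, 3)
  expect_lte(max(rowSums(W != 0)), 3)
  # signals that are exact 1-sparse combinations are coded exactly
  W1 <- matrix(0, 20, 12)
  for (i in 1:20) W1[i, sample(12, 1)] <- runif(1, 0.5, 2)
  X1 <- W1 %*% dict$atoms
  Wr <- omp_code(X1, dict, 1)
  expect_lt(max(abs(Wr - W1)), 1e-8)
})

test_that("K-SVD recovers a planted dictionary from 1-sparse data", {
  set.seed(15)
  true <- patch_dictionary(matrix(rnorm(8 * 16), 8), 4)
  coefs <- matrix(0, 400, 8)
  for (i in 1:400) coefs[i, sample(8, 1)] <- runif(1, 0.5, 2)
  sigs <- coefs %*% true$atoms
  imgs <- lapply(seq_len(nrow(sigs)), function(i) matrix(sigs[i, ], 4, 4))
  learned <- learn_dictionary(imgs, 8, 4, sparsity_target = 1,
                              n_epochs = 15, seed = 3)
  co <- abs(learned$atoms %*% t(true$atoms))
  expect_gt(mean(apply(co, 2, max)), 0.99)
  expect_equal(unname(rowSums(learned$atoms^2)), rep(1, 8))
  tr <- attr(learned, "train_error")
  expect_true(all(diff(tr) <= 1e-10))
})

test_that("K-SVD training is deterministic and rejects degenerate data", {
  imgs <- lapply(1:4, function(s) {
    as.matrix(make_phantom("piecewise_disks", 32, seed = s))
  })
  d1 <- learn_dictionary(imgs, 6, 4, sparsity_target = 2, n_epochs = 2,
                         seed = 11)
  d2 <- learn_dictionary(imgs, 6, 4, sparsity_target = 2, n_epochs = 2,
                         seed = 11)
  expect_identical(d1$atoms, d2$atoms)
  expect_error(learn_dictionary(matrix(1, 32, 32), 4, 4), "degenerate|constant")
  expect_error(learn_dictionary(matrix(rnorm(64), 8), 40, 4), "training patches")
})
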
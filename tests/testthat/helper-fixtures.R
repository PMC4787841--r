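rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(b)), .Machine$double.eps)
}

# Gaussian-smoothed seeded random field (a "generic" image without the
# white-noise aliasing that no interpolating projector can resolve)
smooth_random_image <- function(n, seed = 1, sd = 1.5) {
  withr::with_seed(seed, {
    img <- matrix(stats::rnorm(n * n), n)
    k <- stats::dnorm(-4:4, sd = sd)
    k <- outer(k, k); k <- k / sum(k)
    pad <- matrix(0, n + 8, n + 8)
    pad[5:(n + 4), 5:(n + 4)] <- img
    out <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      out[i, j] <- sum(pad[i:(i + 8), j:(j + 8)] * k)
    }
    out
  })
}

# memoized expensive fixtures shared between test files (built once per run)
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# the standard corrupted acquisition used by the solver and acceptance tests
case1_small <- function() {
  cached_fixture("case1_small", ring_scenario(1, n = 64, n_angles = 90,
                                              seed = 7))
}

case1_full <- function() {
  cached_fixture("case1_full", ring_scenario(1, n = 128, n_angles = 180,
                                             seed = 1))
}

# reference TV reconstructions on the full case-1 fixture (ring correction
# on and frozen off), shared by the ring-capture and energy tests
tv_full_runs <- function() {
  cached_fixture("tv_full_runs", {
    sc <- case1_full()
    cfg_on <- solver_config(beta = 0.1, beta_rings = 0.5, n_iter = 500L)
    cfg_off <- solver_config(beta = 0.1, beta_rings = 0.5, n_iter = 500L,
                             correct_rings = FALSE)
    list(scenario = sc,
         on = reconstruct_tv_rings(sc$corrupt, cfg_on),
         off = reconstruct_tv_rings(sc$corrupt, cfg_off))
  })
}

# a small dictionary trained on phantom slices, for the DL solver tests
phantom_dictionary <- function() {
  cached_fixture("phantom_dictionary", {
    train <- c(lapply(1:6, function(s) {
      as.matrix(make_phantom("piecewise_disks", 64, seed = s + 100))
    }), lapply(1:2, function(s) {
      as.matrix(make_phantom("textured", 64, seed = s + 200))
    }))
    learn_dictionary(train, n_atoms = 48L, w = 8L, sparsity_target = 4L,
                     n_epochs = 8L, seed = 1L, stride = 4L)
  })
}

# DL reconstructions (ring correction on / frozen) on the small fixture
dl_small_runs <- function() {
  cached_fixture("dl_small_runs", {
    sc <- case1_small()
    dict <- phantom_dictionary()
    cfg_on <- solver_config(beta = 0.05, beta_rings = 0.5, n_iter = 200L,
                            rho = 0.5)
    cfg_off <- solver_config(beta = 0.05, beta_rings = 0.5, n_iter = 200L,
                             rho = 0.5, correct_rings = FALSE)
    list(scenario = sc, dict = dict,
         on = reconstruct_dl_rings(sc$corrupt, dict, cfg_on),
         off = reconstruct_dl_rings(sc$corrupt, dict, cfg_off))
  })
}

# first iteration at which the energy trace has closed all but `tol` of the
# gap between its initial and best value
iterations_to_tolerance <- function(trace, tol = 1e-3) {
  gap <- (trace - min(trace)) / (trace[1] - min(trace))
  which(gap <= tol)[1]
}
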
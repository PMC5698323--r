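test_that("delay embedding builds the lag matrix with the documented shape", {
  e <- delay_embed(c(1, 2, 3, 4), E = 2, tau = 1)
  # rows are (x[t], x[t-1]) for t = 2..4; z-scored columns of (2,3,4),(1,2,3)
  z <- (c(1, 2, 3, 4) - mean(1:4)) / sd(1:4)
  expect_equal(e$vectors, cbind(z[2:4], z[1:3]))
  expect_identical(e$index_map, 2:4)

  # E = 1 degenerates to the z-scored series itself
  e1 <- delay_embed(c(5, 1, 4, 2, 8), E = 1)
  expect_equal(as.numeric(e1$vectors), as.numeric(scale(c(5, 1, 4, 2, 8))))

  # row count contract: n - (E-1) * tau
  x <- rnorm(45)
  expect_identical(nrow(delay_embed(x, E = 3, tau = 1)$vectors), 43L)
  expect_identical(nrow(delay_embed(x, E = 4, tau = 3)$vectors), 36L)

  expect_error(delay_embed(1:4, E = 4, tau = 2), "too short")

  # a paleo_ts is reversed into oldest-first dynamical order before embedding
  ts <- paleo_ts(c(0, 1, 2, 3), c(10, 20, 30, 40))  # oldest value 40 at 3 Ma
  ets <- delay_embed(ts, E = 1)
  expect_equal(as.numeric(ets$vectors), as.numeric(scale(c(40, 30, 20, 10))))
})

test_that("simplex projection handles exact matches, symmetry, and convexity", {
  # zero-distance dominance: query identical to a library row
  lib <- rbind(c(0, 0), c(5, 5), c(6, 5), c(5, 6), c(9, 9))
  tg <- c(7, 1, 2, 3, 4)
  expect_equal(simplex_predict(lib, tg, query = rbind(c(0, 0))), 7)

  # two equidistant neighbours with targets 2 and 4 (E = 1): prediction 3
  expect_equal(simplex_predict(matrix(c(-1, 1, 5)), c(2, 4, 100),
                               query = matrix(0)), 3)

  # predictions are convex combinations of neighbour targets
  set.seed(31)
  for (i in 1:20) {
    inst <- random_simplex_instance()
    p <- simplex_predict(inst$lib, inst$targets, query = inst$query)
    expect_true(all(p >= min(inst$targets) - 1e-12))
    expect_true(all(p <= max(inst$targets) + 1e-12))
  }

  # too few usable neighbours is a size error (E = 1 needs 2 neighbours)
  expect_error(simplex_predict(matrix(1), 1, query = matrix(0)),
               "neighbours")
})

test_that("simplex projection matches the brute-force oracle on random instances", {
  set.seed(32)
  for (i in 1:50) {
    inst <- random_simplex_instance()
    # external queries
    expect_equal(simplex_predict(inst$lib, inst$targets, query = inst$query),
                 oracle_simplex(inst$lib, inst$targets, inst$query),
                 tolerance = 1e-12)
    # leave-one-out over the library itself
    expect_equal(simplex_predict(inst$lib, inst$targets),
                 oracle_simplex(inst$lib, inst$targets, inst$lib,
                                exclude = seq_len(nrow(inst$lib))),
                 tolerance = 1e-12)
  }
})

test_that("self cross-mapping of a deterministic series is near-perfect", {
  sys <- coupled_logistic(seed = 3, beta_ab = 0)
  r <- cross_map(sys$A, sys$A, E = 3, library_size = 43, n_replicates = 1,
                 seed = 1)
  expect_gt(r$rho_mean, 0.99)
})

test_that("cross-map skill on independent white noise is centred near zero", {
  rhos <- vapply(1:30, function(s) {
    p <- ar1_null(phi = 0, n = 45, seed = s)
    cross_map(p$A, p$B, E = 3, library_size = 43, n_replicates = 1,
              seed = 1)$rho_mean
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.25)
})

test_that("cross-map skill grows with library size on the coupled benchmark", {
  for (s in c(2, 7, 19)) {
    sys <- coupled_logistic(seed = s)
    r10 <- cross_map(sys$A, sys$B, E = 3, library_size = 10,
                     n_replicates = 100, seed = 1)
    r40 <- cross_map(sys$A, sys$B, E = 3, library_size = 40,
                     n_replicates = 100, seed = 1)
    expect_gt(r40$rho_mean, r10$rho_mean)
  }
})

test_that("the ccm ladder honours its shape and ordering contracts", {
  sys <- coupled_logistic(seed = 5)
  fit <- ccm(sys$A, sys$B, E = 3, library_sizes = seq(5, 43, by = 4),
             n_replicates = 50, seed = 9)
  expect_s3_class(fit, "ccm")
  expect_length(fit$rho_mean, length(fit$library_sizes))
  expect_true(all(abs(fit$rho_replicates) <= 1))
  expect_lte(fit$rho_max, max(fit$rho_replicates))
  expect_equal(fit$rho_terminal, fit$rho_mean[length(fit$rho_mean)])
  # convergence: positive Spearman trend of mean skill with library size
  expect_gt(cor(fit$library_sizes, fit$rho_mean, method = "spearman"), 0)
  expect_error(ccm(sys$A, sys$B, E = 3, library_sizes = c(10, 9)),
               "increasing")
  expect_error(cross_map(sys$A, sys$B, E = 3, library_size = 4), "E \\+ 2")
})

test_that("identical seeds reproduce a CCM fit bit-for-bit", {
  sys <- coupled_logistic(seed = 12)
  f1 <- ccm(sys$A, sys$B, E = 2, library_sizes = c(10, 20, 40),
            n_replicates = 30, seed = 77)
  f2 <- ccm(sys$A, sys$B, E = 2, library_sizes = c(10, 20, 40),
            n_replicates = 30, seed = 77)
  expect_identical(f1$rho_replicates, f2$rho_replicates)
  f3 <- ccm(sys$A, sys$B, E = 2, library_sizes = c(10, 20, 40),
            n_replicates = 30, seed = 78)
  expect_false(identical(f1$rho_replicates, f3$rho_replicates))
})

test_that("cross-map skill is invariant to affine transforms of either series", {
  sys <- coupled_logistic(seed = 8)
  base <- cross_map(sys$A, sys$B, E = 3, library_size = 30,
                    n_replicates = 20, seed = 4)
  affA <- paleo_ts(sys$A$ages, 5 - 2 * sys$A$values, name = "A")
  affB <- paleo_ts(sys$B$ages, 0.1 * sys$B$values + 7, name = "B")
  expect_equal(cross_map(affA, sys$B, E = 3, library_size = 30,
                         n_replicates = 20, seed = 4)$rho_replicates,
               base$rho_replicates, tolerance = 1e-9)
  expect_equal(cross_map(sys$A, affB, E = 3, library_size = 30,
                         n_replicates = 20, seed = 4)$rho_replicates,
               base$rho_replicates, tolerance = 1e-9)
})

test_that("directional asymmetry holds on the unidirectional benchmark", {
  hits <- vapply(1:50, function(s) {
    sys <- coupled_logistic(seed = s)  # truth: B -> A
    true_dir <- cross_map(sys$A, sys$B, E = 3, library_size = 43,
                          n_replicates = 1, seed = 1)$rho_mean
    false_dir <- cross_map(sys$B, sys$A, E = 3, library_size = 43,
                           n_replicates = 1, seed = 1)$rho_mean
    true_dir > false_dir
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the embedding-dimension sensitivity harness runs at E = 2, 3, 4", {
  sys <- coupled_logistic(seed = 6)
  fits <- lapply(c(2, 3, 4), function(E)
    ccm(sys$A, sys$B, E = E, library_sizes = c(20, 40), n_replicates = 20,
        seed = 1))
  expect_identical(vapply(fits, function(f) f$E, integer(1)), c(2L, 3L, 4L))
  expect_true(all(vapply(fits, function(f) f$rho_terminal, numeric(1)) > 0))
})
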
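test_that("sparse low-rank generator hits the target rank exactly", {
  expect_equal(unclass(gen_sparse_lowrank(rank = 0)),
               matrix(0, 50, 20), ignore_attr = TRUE)
  X <- gen_sparse_lowrank(seed = 1)
  expect_equal(numerical_rank(X), 6L)
  expect_equal(dim(X), c(50L, 20L))
  expect_identical(unclass(gen_sparse_lowrank(seed = 4)),
                   unclass(gen_sparse_lowrank(seed = 4)))
  expect_error(gen_sparse_lowrank(rank = 25), "rank")
  expect_error(gen_sparse_lowrank(factor_sparsity = 0), "factor_sparsity")
})

test_that("factor sparsity propagates to the product's zero fraction", {
  zero_frac <- vapply(1:10, function(s) {
    mean(unclass(gen_sparse_lowrank(q = 40, n = 4, N_T = 10, rank = 3,
                                    factor_sparsity = 0.3, seed = s)) == 0)
  }, numeric(1))
  # entries are nonzero only where some factor pair overlaps; the expected
  # zero fraction is at least (1 - 0.3)^2 minus slack
  expect_gte(mean(zero_frac), (1 - 0.3)^2 - 0.1)
})

test_that("sparse corruption hits exactly the requested support", {
  X <- gen_sparse_lowrank(seed = 2)
  none <- add_sparse_corruption(X, rho = 0)
  expect_equal(unclass(none$corrupted), unclass(X), ignore_attr = TRUE)
  expect_true(all(none$corruption == 0))

  cc <- add_sparse_corruption(X, rho = 0.05, amplitude = 1, seed = 3)
  expect_equal(sum(cc$corruption != 0), 50L)  # floor(0.05 * 1000)
  expect_equal(unclass(X) + cc$corruption, unclass(cc$corrupted),
               ignore_attr = TRUE)
  vals <- unique(abs(cc$corruption[cc$corruption != 0]))
  expect_equal(vals, sqrt(mean(unclass(X)^2)), tolerance = 1e-12)

  # norm-matched default: corruption norm equals signal norm
  ccd <- add_sparse_corruption(X, seed = 3)
  expect_equal(frob(ccd$corruption), frob(unclass(X)), tolerance = 1e-10)
  expect_error(add_sparse_corruption(X, rho = 1), "rho")
})

test_that("neural trial rates are sparse, bounded and template-driven", {
  tt <- gen_neural_trials(q = 10, n = 20, N_T = 15, seed = 1)
  expect_true(all(tt$data >= 0))
  expect_lte(max(tt$data), 40)

  # noiseless, fully active, non-eccentric: every block is the shared
  # temporal profile up to a per-neuron scale
  flat <- gen_neural_trials(q = 6, n = 5, N_T = 12, active_fraction = 1,
                            eccentricity = 1, noise = FALSE, seed = 2)
  ref <- flat$data[, 1, ]
  for (s in 2:5) {
    ratio <- flat$data[, s, ] / ref
    expect_lt(max(ratio) - min(ratio), 1e-10)
  }

  # all-zero neuron fraction tracks 1 - active_fraction
  zfrac <- vapply(1:20, function(s) {
    tt <- gen_neural_trials(q = 5, n = 40, N_T = 10, active_fraction = 0.3,
                            seed = s)
    mean(apply(tt$data, 2, function(b) all(b == 0)))
  }, numeric(1))
  expect_lt(abs(mean(zfrac) - 0.7), 0.1)

  expect_error(gen_neural_trials(active_fraction = 0), "active_fraction")
  expect_error(gen_neural_trials(rate_range = c(0, 80)), "rate_range")
})

test_that("perturbation panels propagate single-target forcings through A", {
  A <- diag(c(-1, -0.8, -1.2))
  # no perturbations: wild-type dynamics only
  m0 <- network_model(A, x0 = c(1, 1, 1), N_T = 15)
  p0 <- simulate_perturbation_panel(m0)
  expect_equal(dim(p0)[1], 1L)

  # diagonal A: perturbing species 2 leaves the others at wild-type
  m1 <- network_model(A, perturbations = list(
    list(target = 2, effect = 1, sign = -1, onset = 0)),
    x0 = c(1, 1, 1), N_T = 15)
  p1 <- simulate_perturbation_panel(m1)
  expect_equal(p1$data[2, 1, ], p1$data[1, 1, ], tolerance = 1e-10)
  expect_equal(p1$data[2, 3, ], p1$data[1, 3, ], tolerance = 1e-10)
  expect_gt(max(abs(p1$data[2, 2, ] - p1$data[1, 2, ])), 0.1)

  # edge 1 -> 2 only: perturbing 1 reaches 2; perturbing 2 never reaches 1
  A2 <- matrix(c(-1, 0.8, 0, -1), 2, 2)   # A2[2,1] = 0.8
  m2 <- network_model(A2, perturbations = list(
    list(target = 1, effect = 1), list(target = 2, effect = 1)),
    x0 = c(0.5, 0.5), N_T = 20)
  p2 <- simulate_perturbation_panel(m2)
  expect_gt(max(abs(p2$data[2, 2, ] - p2$data[1, 2, ])), 1e-3)  # 1 propagates to 2
  expect_equal(p2$data[3, 1, ], p2$data[1, 1, ], tolerance = 1e-10)  # 2 never to 1

  expect_error(simulate_perturbation_panel(network_model(diag(2))), "stable")
  expect_error(network_model(diag(-1, 2), perturbations = list(list(effect = 1))),
               "exactly one species")
})

test_that("detection and subtype generators are reproducible and structured", {
  g1 <- gen_template_trials(seed = 5)
  g2 <- gen_template_trials(seed = 5)
  expect_identical(unclass(g1$X), unclass(g2$X))
  expect_equal(length(g1$aberrant), 8L)
  expect_equal(dim(g1$pattern), c(6L, 12L))

  st <- gen_template_stream(g1$pattern, n_onsets = 10, seed = 5)
  expect_equal(length(st$onsets), 10L)
  expect_true(all(diff(st$onsets) > ncol(g1$pattern)))

  sp <- gen_subtype_panel(seed = 5)
  expect_equal(table(sp$subtype), table(rep(1:2, each = 20)), ignore_attr = TRUE)
  # subtype signatures live on disjoint supports
  s1 <- which(colSums(sp$signature[sp$subtype == 1, ] != 0) > 0)
  s2 <- which(colSums(sp$signature[sp$subtype == 2, ] != 0) > 0)
  expect_length(intersect(s1, s2), 0)
})

test_that("generator seed streams are independent and stable", {
  expect_identical(split_seed(1, "projection"), split_seed(1, "projection"))
  expect_false(split_seed(1, "projection") == split_seed(1, "corruption"))
  expect_false(split_seed(1, "projection") == split_seed(2, "projection"))
  expect_true(split_seed(.Machine$integer.max, "x", 99) < 2^31)
})
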
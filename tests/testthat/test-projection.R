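test_that("projection draws are deterministic and validated", {
  P1 <- make_projection(n = 2, m = 2, N_T = 5, seed = 0)
  P2 <- make_projection(n = 2, m = 2, N_T = 5, seed = 0)
  expect_identical(P1$psi, P2$psi)
  expect_false(identical(P1$psi, make_projection(n = 2, N_T = 5, seed = 1)$psi))
  expect_error(make_projection(n = 2, m = 3, N_T = 5), "m > n")
  expect_error(make_projection(n = 2, m = 2, N_T = 5, distribution = "cauchy"))
  Pid <- make_projection(n = 3, N_T = 4, distribution = "identity")
  expect_equal(Pid$psi, diag(3))
})

test_that("Gaussian scaling keeps projected column norms near one", {
  P <- make_projection(n = 64, m = 16, N_T = 1, seed = 2)
  expect_lt(abs(mean(sqrt(colSums(P$psi^2))) - 1), 0.2)
})

test_that("blockwise application equals the dense Kronecker operator", {
  set.seed(21)
  for (cfg in list(c(4, 4, 5), c(6, 3, 7), c(5, 5, 1))) {
    n <- cfg[1]; m <- cfg[2]; nt <- cfg[3]
    X <- data_matrix(matrix(rnorm(8 * n * nt), 8, n * nt), n, nt)
    P <- make_projection(n = n, m = m, N_T = nt, seed = 3)
    Y <- apply_projection(X, P)
    Ydense <- unclass(X) %*% projection_dense(P)
    expect_lt(max(abs(unclass(Y) - Ydense)), 1e-12)
    expect_equal(n_species(Y), m)
    expect_equal(n_timepoints(Y), nt)
  }
})

test_that("identity and permutation operators act as expected on blocks", {
  X <- data_matrix(matrix(1:12, 2, 6), n_species = 3, n_timepoints = 2)
  Pid <- make_projection(n = 3, N_T = 2, distribution = "identity")
  expect_equal(unclass(apply_projection(X, Pid)), unclass(X), ignore_attr = TRUE)

  perm <- Pid
  perm$psi <- diag(3)[c(2, 3, 1), ]        # block j of Y = block perm(j) of X
  Y <- apply_projection(X, perm)
  expect_equal(species_block(Y, 1), species_block(X, 2), ignore_attr = TRUE)
  expect_equal(species_block(Y, 2), species_block(X, 3), ignore_attr = TRUE)
  expect_equal(species_block(Y, 3), species_block(X, 1), ignore_attr = TRUE)

  # m = 1 summing operator on two scalar blocks: row (3, 4) -> 7
  Xs <- data_matrix(matrix(c(3, 4), 1, 2), 2, 1)
  Psum <- make_projection(n = 2, m = 1, N_T = 1, seed = 0)
  Psum$psi <- matrix(c(1, 1), 1, 2)
  expect_equal(as.numeric(apply_projection(Xs, Psum)), 7)
})

test_that("projection is linear and never mixes time within a block", {
  set.seed(22)
  n <- 4; nt <- 6
  P <- make_projection(n = n, N_T = nt, seed = 5)
  X1 <- data_matrix(matrix(rnorm(5 * n * nt), 5, n * nt), n, nt)
  X2 <- data_matrix(matrix(rnorm(5 * n * nt), 5, n * nt), n, nt)
  lhs <- apply_projection(data_matrix(2 * unclass(X1) - 3 * unclass(X2), n, nt), P)
  rhs <- 2 * unclass(apply_projection(X1, P)) - 3 * unclass(apply_projection(X2, P))
  expect_equal(unclass(lhs), rhs, tolerance = 1e-12, ignore_attr = TRUE)

  # species i carries a spike at time t_i: output block j must be the
  # psi-weighted sum of those spikes, still at their original times
  spikes <- c(2, 5, 1, 4)
  Xs <- matrix(0, 1, n * nt)
  for (i in seq_len(n)) Xs[1, (i - 1) * nt + spikes[i]] <- 1
  Y <- apply_projection(data_matrix(Xs, n, nt), P)
  for (j in seq_len(n)) {
    expected <- numeric(nt)
    for (i in seq_len(n)) expected[spikes[i]] <- expected[spikes[i]] + P$psi[j, i]
    expect_equal(as.numeric(species_block(Y, j)), expected, tolerance = 1e-12)
  }
})

test_that("square projections invert to round-trip accuracy", {
  set.seed(23)
  X <- data_matrix(matrix(rnorm(10 * 12), 10, 12), 4, 3)
  P <- make_projection(n = 4, N_T = 3, seed = 0)
  expect_lt(rel_err(unclass(invert_projection(apply_projection(X, P), P)),
                    unclass(X)), 1e-10)

  Pid <- make_projection(n = 4, N_T = 3, distribution = "identity")
  expect_equal(unclass(invert_projection(X, Pid)), unclass(X),
               tolerance = 1e-12, ignore_attr = TRUE)
  P2 <- Pid; P2$psi <- 2 * diag(4)
  expect_equal(unclass(invert_projection(X, P2)), unclass(X) / 2,
               tolerance = 1e-12, ignore_attr = TRUE)

  Pc <- make_projection(n = 4, m = 2, N_T = 3, seed = 0)
  expect_error(invert_projection(X, Pc), "cannot be inverted")
})

test_that("projection approximately preserves pairwise row distances", {
  set.seed(24)
  n <- 64; nt <- 2; q <- 50
  X <- data_matrix(matrix(rnorm(q * n * nt), q, n * nt), n, nt)
  P <- make_projection(n = n, m = n / 2, N_T = nt, seed = 7)
  Y <- unclass(apply_projection(X, P))
  pairs <- cbind(sample(q, 50, replace = TRUE), sample(q, 50, replace = TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  ratio <- apply(pairs, 1, function(ij) {
    sqrt(sum((Y[ij[1], ] - Y[ij[2], ])^2)) /
      sqrt(sum((unclass(X)[ij[1], ] - unclass(X)[ij[2], ])^2))
  })
  expect_gte(mean(ratio >= 0.5 & ratio <= 2), 0.95)
})

test_that("projection de-eccentrifies species-block scales", {
  cv <- function(x) sd(x) / mean(x)
  block_norms <- function(X) {
    vapply(seq_len(n_species(X)), function(i) frob(species_block(X, i)),
           numeric(1))
  }
  wins <- 0L
  for (s in 1:20) {
    set.seed(s)
    n <- 16; nt <- 8; q <- 30
    scales <- 10^seq(-1, 1, length.out = n)   # block norms span 100x
    X <- matrix(rnorm(q * n * nt), q, n * nt)
    for (i in seq_len(n))
      X[, (i - 1) * nt + seq_len(nt)] <- scales[i] * X[, (i - 1) * nt + seq_len(nt)]
    X <- data_matrix(X, n, nt)
    Y <- apply_projection(X, make_projection(n = n, N_T = nt, seed = s))
    if (cv(block_norms(Y)) < cv(block_norms(X))) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("the projected pipeline reduces to plain PCP under the identity law", {
  set.seed(25)
  X <- data_matrix(matrix(rnorm(15 * 8), 15, 8), 2, 4)
  Pid <- make_projection(n = 2, N_T = 4, distribution = "identity")
  drp <- rp_rpca(X, Pid)
  dpl <- pcp_decompose(X)
  expect_equal(unclass(drp$L), unclass(dpl$L), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unclass(drp$S), unclass(dpl$S), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(drp$invertible)
})

test_that("compressive projections return flagged projected-space results", {
  set.seed(26)
  X <- data_matrix(matrix(rnorm(20 * 12), 20, 12), 4, 3)
  P <- make_projection(n = 4, m = 2, N_T = 3, seed = 1)
  d <- rp_rpca(X, P)
  expect_false(d$invertible)
  expect_equal(ncol(d$L), 2 * 3)
  expect_lte(rel_err(unclass(d$L) + unclass(d$S),
                     unclass(apply_projection(X, P))), 1e-6)
})

test_that("back-projected components reassemble the input", {
  set.seed(27)
  inst <- benchmark_instance(seed = 101)
  d <- rp_rpca(inst$corrupted, inst$P, lam = lambda_discounted)
  expect_lte(rel_err(unclass(d$L) + unclass(d$S), unclass(inst$corrupted)), 1e-5)
})
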
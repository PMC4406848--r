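# Shared fixture builders (everything generated in code at test time).

frob <- function(A) sqrt(sum(A^2))
rel_err <- function(A, B) frob(A - B) / frob(B)

# Incoherent low-rank + spread sparse oracle instance.  PCP's exact-recovery
# guarantee assumes the low-rank part is incoherent (no spiky singular
# vectors) and the corruption support is spread out; at 20 x 20 a plain
# Gaussian draw violates those assumptions often enough to matter, so the
# construction enforces them: Haar orthonormal factors are resampled until
# every row leverage is at most `lev_cap` times the flat value, and the
# corruption support takes one entry per row and per column (still an
# exactly 5% fraction at 20 x 20).
oracle_instance <- function(d = 20, r = 2, amp = 3, seed = 1, lev_cap = 2.5) {
  set.seed(seed)
  lever <- function(Q) max(rowSums(Q^2)) * nrow(Q) / ncol(Q)
  draw_factor <- function() {
    repeat {
      Q <- qr.Q(qr(matrix(rnorm(d * r), d, r)))
      if (lever(Q) <= lev_cap) return(Q)
    }
  }
  U <- draw_factor(); V <- draw_factor()
  L0 <- 5 * U %*% t(V)
  S0 <- matrix(0, d, d)
  S0[cbind(seq_len(d), sample(d))] <-
    sample(c(-1, 1), d, replace = TRUE) * mean(abs(L0)) * amp
  list(L0 = L0, S0 = S0, M = L0 + S0)
}

# The sparse low-rank benchmark instance: rank-6 50 x 20 matrix, 5%
# corruption, invertible Gaussian species mixing.
benchmark_instance <- function(seed, amplitude = NULL) {
  X <- gen_sparse_lowrank(seed = seed)
  cc <- add_sparse_corruption(X, amplitude = amplitude, seed = seed)
  P <- make_projection(n = 2, N_T = 10, seed = seed)
  list(X = X, corrupted = cc$corrupted, corruption = cc$corruption, P = P)
}

lambda_benchmark <- default_lambda(50, 2, 10)      # 0.1414
lambda_discounted <- 0.8 * default_lambda(50, 2, 10)  # 0.1131

modal <- function(x) as.integer(names(which.max(table(x))))
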
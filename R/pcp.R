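#' Default PCP tuning parameter
#'
#' The standard rule for the weight balancing the nuclear norm of the
#' low-rank part against the l1 norm of the sparse part:
#' `lambda = 1 / sqrt(max(q, n * N_T))` for a `q` by `n * N_T` matrix.
#' Smaller values (e.g. a 20% discount, `0.8 * default_lambda(...)`)
#' penalize the sparse component less and drive the recovered rank down,
#' which helps when the input is itself sparse.
#'
#' @param q number of trials (rows).
#' @param n number of species.
#' @param N_T number of time points per species block.
#' @return positive scalar lambda.
#' @examples
#' default_lambda(50, 2, 10)        # 0.1414
#' 0.8 * default_lambda(50, 2, 10)  # 0.1131, the discounted choice
#' @export
default_lambda <- function(q, n, N_T) {
  if (any(c(q, n, N_T) < 1) || any(!is.finite(c(q, n, N_T))))
    stop("q, n and N_T must be positive", call. = FALSE)
  1 / sqrt(max(q, n * N_T))
}

#' Elementwise soft-thresholding (proximal operator of the l1 norm)
#'
#' `sign(a) * pmax(abs(a) - tau, 0)` applied entrywise.
#'
#' @param A numeric matrix or vector.
#' @param tau nonnegative threshold.
#' @return object of the same shape as `A`.
#' @export
soft_threshold <- function(A, tau) {
  if (tau < 0) stop("tau must be nonnegative", call. = FALSE)
  sign(A) * pmax(abs(A) - tau, 0)
}

#' Singular-value thresholding (proximal operator of the nuclear norm)
#'
#' Computes the SVD of `A`, shrinks each singular value by `tau` (flooring
#' at zero) and reconstructs.  Singular-vector signs are fixed so that the
#' largest-magnitude element of each retained left singular vector is
#' positive, making repeated runs bit-reproducible regardless of the
#' LAPACK sign convention.
#'
#' @param A numeric matrix.
#' @param tau nonnegative shrinkage amount.
#' @return matrix of the same shape as `A`.
#' @export
singular_value_threshold <- function(A, tau) {
  if (tau < 0) stop("tau must be nonnegative", call. = FALSE)
  if (!all(is.finite(A))) stop("non-finite entries in input", call. = FALSE)
  sv <- svd(A)
  d <- pmax(sv$d - tau, 0)
  k <- sum(d > 0)
  if (k == 0L) return(array(0, dim(A)))
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sign(U[which.max(abs(U[, j])), j])
    if (s < 0) { U[, j] <- -U[, j]; V[, j] <- -V[, j] }
  }
  U %*% (d[seq_len(k)] * t(V))
}

#' Numerical rank
#'
#' Number of singular values exceeding `rel_tol` times the largest; 0 for
#' the zero matrix.  Used to report the rank of recovered low-rank
#' components, where tiny singular values are solver noise.
#'
#' @param A numeric matrix.
#' @param rel_tol relative tolerance in (0, 1); default `1e-6`.
#' @return nonnegative integer.
#' @export
numerical_rank <- function(A, rel_tol = 1e-6) {
  if (rel_tol <= 0 || rel_tol >= 1) stop("rel_tol must be in (0,1)", call. = FALSE)
  d <- svd(A, nu = 0, nv = 0)$d
  if (length(d) == 0L || d[1] == 0) return(0L)
  sum(d > rel_tol * d[1])
}

#' Principal Component Pursuit
#'
#' Solves `min ||L||_* + lambda ||S||_1  s.t.  M = L + S` by the inexact
#' augmented-Lagrangian method: alternating singular-value thresholding on
#' `L` and soft-thresholding on `S` with a dual update, penalty
#' `mu` initialized at `1.25 / sigma_max(M)` and grown geometrically by
#' 1.5 -- but only once the sparse update has stabilized
#' (`min(mu, sqrt(mu)) * ||S_k - S_{k-1}||_F / ||M||_F < 1e-5`), which
#' keeps the iterates minimizing the objective instead of merely racing
#' to feasibility -- stopping when the relative Frobenius residual
#' `||M - L - S||_F / ||M||_F` drops below `tol`.
#'
#' @param M numeric matrix or [data_matrix()]; all entries finite.
#' @param lam positive weight on the sparse component; default
#'   [default_lambda()] computed from the matrix shape.
#' @param tol relative Frobenius residual at convergence; default `1e-7`.
#' @param max_iter iteration cap; default 1000.  If reached without
#'   convergence the result is returned with `converged = FALSE` and a
#'   warning.
#' @return a `pcp_decomposition`: list with components `L`, `S`, `lam`,
#'   `iterations`, `residual`, `converged`.
#' @examples
#' M <- tcrossprod(rnorm(20), rnorm(20))  # rank 1, nothing sparse
#' d <- pcp_decompose(M)
#' numerical_rank(d$L)
#' @export
pcp_decompose <- function(M, lam = NULL, tol = 1e-7, max_iter = 1000L) {
  meta <- if (inherits(M, "data_matrix"))
    list(n = n_species(M), nt = n_timepoints(M)) else NULL
  M <- if (inherits(M, "data_matrix")) unclass_matrix(M) else as.matrix(M)
  if (!all(is.finite(M))) stop("non-finite entries in input", call. = FALSE)
  if (is.null(lam)) lam <- 1 / sqrt(max(dim(M)))
  if (lam <= 0) stop("lam must be positive", call. = FALSE)

  normF <- function(A) sqrt(sum(A^2))
  nM <- normF(M)
  if (nM == 0) {
    return(new_pcp(L = M, S = M, lam = lam, iterations = 0L,
                   residual = 0, converged = TRUE, meta = meta))
  }
  sigma1 <- svd(M, nu = 0, nv = 0)$d[1]
  mu <- 1.25 / sigma1
  mu_max <- mu * 1e7
  rho <- 1.5
  # dual start of Lin et al.'s inexact ALM: Y = M / J(M)
  Y <- M / max(sigma1, max(abs(M)) / lam)
  L <- array(0, dim(M)); S <- array(0, dim(M))
  it <- 0L; res <- Inf
  while (it < max_iter) {
    it <- it + 1L
    L <- singular_value_threshold(M - S + Y / mu, 1 / mu)
    S_new <- soft_threshold(M - L + Y / mu, lam / mu)
    dS <- normF(S_new - S)
    S <- S_new
    Z <- M - L - S
    Y <- Y + mu * Z
    # grow the penalty only once the sparse iterate has settled at the
    # current mu; unconditional growth freezes the iterates at a feasible
    # but suboptimal point
    if (min(mu, sqrt(mu)) * dS / nM < 1e-5) mu <- min(mu * rho, mu_max)
    res <- normF(Z) / nM
    if (res <= tol) break
  }
  conv <- res <= tol
  if (!conv)
    warning(sprintf("PCP did not converge in %d iterations (residual %.3g > tol %.3g)",
                    max_iter, res, tol), call. = FALSE)
  new_pcp(L = L, S = S, lam = lam, iterations = it, residual = res,
          converged = conv, meta = meta)
}

new_pcp <- function(L, S, lam, iterations, residual, converged,
                    meta = NULL, extra = list()) {
  if (!is.null(meta)) {
    L <- data_matrix(L, meta$n, meta$nt)
    S <- data_matrix(S, meta$n, meta$nt)
  }
  structure(c(list(L = L, S = S, lam = lam, iterations = iterations,
                   residual = residual, converged = converged), extra),
            class = "pcp_decomposition")
}

#' @export
print.pcp_decomposition <- function(x, ...) {
  cat(sprintf(
    "PCP decomposition: %d x %d, lambda = %.4g\n  rank(L) = %d, nnz(S) = %d (%.1f%%)\n  %d iterations, residual %.3g, converged: %s\n",
    nrow(x$L), ncol(x$L), x$lam, numerical_rank(x$L), sum(x$S != 0),
    100 * mean(x$S != 0), x$iterations, x$residual, x$converged))
  if (!is.null(x$invertible))
    cat(sprintf("  random-projection pipeline, back-projected: %s\n", x$invertible))
  invisible(x)
}

#' Zero out small entries of a sparse component for display
#'
#' Heat maps of the aberrant component are easier to read when entries
#' below a fraction of the largest magnitude are blanked.
#'
#' @param S numeric matrix (typically the `S` of a decomposition).
#' @param frac entries with `|S| < frac * max(abs(S))` are set to zero;
#'   default 0.1.
#' @return thresholded matrix.
#' @export
threshold_sparse <- function(S, frac = 0.1) {
  stopifnot(frac >= 0, frac <= 1)
  m <- max(abs(S))
  if (m == 0) return(S)
  S[abs(S) < frac * m] <- 0
  S
}
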
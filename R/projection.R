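#' Random species-mixing projection operator
#'
#' Draws an `m` by `n` matrix `Psi` with i.i.d. entries (default Gaussian
#' with variance `1/m`, the scaling under which projected column norms
#' concentrate near the original ones) and represents the Kronecker
#' operator `R = t(Psi) %x% I_NT` that acts on species-major data
#' matrices: `Y = X %*% R` mixes species blocks while preserving the time
#' order within every block.  With `m = n` the operator is invertible and
#' a decomposition of `Y` can be mapped back to species space; with
#' `m < n` it compresses.  In invertible mode `Psi` is resampled (from a
#' derived sub-seed) until it is numerically nonsingular.
#'
#' @param n input species dimension.
#' @param m output species dimension, `1 <= m <= n`; default `n`
#'   (invertible mode).
#' @param N_T time points per species block.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param distribution `"gaussian"` (i.i.d. N(0, 1/m)) or `"identity"`
#'   (debug law, requires `m = n`).
#' @return a `projection_operator`: list with `psi`, `m`, `n`, `N_T`,
#'   `seed`, `distribution`.
#' @examples
#' P <- make_projection(n = 2, N_T = 10, seed = 1)
#' P$psi
#' @export
make_projection <- function(n, m = n, N_T, seed = 0L,
                            distribution = c("gaussian", "identity")) {
  distribution <- match.arg(distribution)
  n <- as.integer(n); m <- as.integer(m); N_T <- as.integer(N_T)
  if (n < 1L || m < 1L || N_T < 1L)
    stop("n, m and N_T must be positive", call. = FALSE)
  if (m > n) stop("m > n: the projection must not expand the species dimension",
                  call. = FALSE)
  if (distribution == "identity") {
    if (m != n) stop("identity law requires m = n", call. = FALSE)
    psi <- diag(n)
  } else {
    psi <- NULL
    for (attempt in 0:99) {
      cand <- with_seed(split_seed(seed, "projection", attempt),
                        matrix(rnorm(m * n, sd = 1 / sqrt(m)), m, n))
      if (m < n || is_nonsingular(cand)) { psi <- cand; break }
    }
    if (is.null(psi))
      stop("failed to draw a nonsingular square Psi", call. = FALSE)
  }
  structure(list(psi = psi, m = m, n = n, N_T = N_T, seed = as.integer(seed),
                 distribution = distribution),
            class = "projection_operator")
}

is_nonsingular <- function(A, max_condition = 1e12) {
  d <- svd(A, nu = 0, nv = 0)$d
  d[length(d)] > 0 && d[1] / d[length(d)] < max_condition
}

#' @export
print.projection_operator <- function(x, ...) {
  cat(sprintf("projection_operator: Psi %d x %d (%s, seed %d), N_T = %d%s\n",
              x$m, x$n, x$distribution, x$seed, x$N_T,
              if (x$m == x$n) ", invertible mode" else ""))
  invisible(x)
}

#' Dense Kronecker expansion of a projection operator
#'
#' Materializes `R = t(Psi) %x% I_NT`, an `n*N_T` by `m*N_T` matrix.
#' Intended for verification on small instances; [apply_projection()]
#' computes `X %*% R` blockwise without forming `R`.
#'
#' @param P a [make_projection()] operator.
#' @return dense numeric matrix `R`.
#' @export
projection_dense <- function(P) {
  stopifnot(inherits(P, "projection_operator"))
  kronecker(t(P$psi), diag(P$N_T))
}

#' Apply a projection operator to a data matrix
#'
#' Computes `Y = X %*% R` with `R = t(Psi) %x% I_NT`, i.e. output species
#' block `j` is `sum_i Psi[j, i] * (block i of X)`.  Implemented blockwise
#' (one `(q*N_T) x n` by `n x m` multiply); the time axis is never mixed.
#'
#' @param X a [data_matrix()] whose block structure matches `P`.
#' @param P a [make_projection()] operator.
#' @return a `data_matrix` of shape `q` by `m * N_T`.
#' @export
apply_projection <- function(X, P) {
  stopifnot(inherits(P, "projection_operator"))
  X <- as_data_matrix(X, P$n, P$N_T)
  if (n_species(X) != P$n || n_timepoints(X) != P$N_T)
    stop(sprintf("block structure mismatch: X is (n=%d, N_T=%d) but Psi expects (n=%d, N_T=%d)",
                 n_species(X), n_timepoints(X), P$n, P$N_T), call. = FALSE)
  Y2 <- unfold_species(X) %*% t(P$psi)
  fold_species(Y2, nrow(X), P$N_T, row_labels = rownames(X))
}

#' Invert a square projection
#'
#' Computes `Y %*% solve(R)` with `solve(R) = solve(t(Psi)) %x% I_NT`,
#' undoing [apply_projection()] exactly (round trip accurate to ~1e-10
#' relative error for well-conditioned `Psi`).  Only defined in
#' invertible mode (`m = n`); an ill-conditioned `Psi` (condition number
#' above 1e8) triggers a warning.
#'
#' @param Y a `data_matrix` in projected space (`m` species blocks).
#' @param P the operator used to produce `Y`.
#' @return a `data_matrix` of shape `q` by `n * N_T`.
#' @export
invert_projection <- function(Y, P) {
  stopifnot(inherits(P, "projection_operator"))
  if (P$m < P$n)
    stop("projection is compressive (m < n) and cannot be inverted", call. = FALSE)
  Y <- as_data_matrix(Y, P$m, P$N_T)
  if (n_species(Y) != P$m || n_timepoints(Y) != P$N_T)
    stop("block structure mismatch between Y and the operator", call. = FALSE)
  kap <- kappa(P$psi, exact = TRUE)
  if (kap > 1e8)
    warning(sprintf("Psi is ill-conditioned (condition number %.3g); inversion may be inaccurate", kap),
            call. = FALSE)
  X2 <- unfold_species(Y) %*% solve(t(P$psi))
  fold_species(X2, nrow(Y), P$N_T, row_labels = rownames(Y))
}

#' RP-RPCA: Principal Component Pursuit on randomly projected data
#'
#' The full projected pipeline: form `Y = X %*% R`, decompose `Y` into a
#' low-rank and a sparse part by [pcp_decompose()], and -- when the
#' operator is square and nonsingular -- map both parts back to species
#' space, `Lbar = L_Y %*% solve(R)` and `Sbar = S_Y %*% solve(R)`, so
#' that `Lbar + Sbar` reproduces `X` to solver tolerance.  Projection
#' de-sparsifies and de-eccentrifies the input, restoring the
#' identifiability assumptions PCP relies on when raw trials are sparse
#' or have wildly uneven species scales.
#'
#' With a compressive operator (`m < n`) the components cannot be mapped
#' back; the projected-space components are returned with
#' `invertible = FALSE`.
#'
#' @inheritParams pcp_decompose
#' @param X a [data_matrix()] (or plain matrix matching `P`'s blocks).
#' @param P a [make_projection()] operator.
#' @return a `pcp_decomposition` with `L`, `S` (back-projected when
#'   invertible, projected-space otherwise), plus `projected` (the raw
#'   `L_Y`, `S_Y`), `invertible`, and solver diagnostics.
#' @examples
#' X <- gen_sparse_lowrank(seed = 1)
#' P <- make_projection(n = 2, N_T = 10, seed = 1)
#' d <- rp_rpca(X, P, lam = 0.8 * default_lambda(50, 2, 10))
#' numerical_rank(d$L)
#' @export
rp_rpca <- function(X, P, lam = NULL, tol = 1e-7, max_iter = 1000L) {
  stopifnot(inherits(P, "projection_operator"))
  X <- as_data_matrix(X, P$n, P$N_T)
  Y <- apply_projection(X, P)
  dec <- pcp_decompose(Y, lam = lam, tol = tol, max_iter = max_iter)
  invertible <- P$m == P$n
  if (invertible) {
    Lbar <- invert_projection(dec$L, P)
    Sbar <- invert_projection(dec$S, P)
    new_pcp(L = unclass_matrix(Lbar), S = unclass_matrix(Sbar),
            lam = dec$lam, iterations = dec$iterations,
            residual = dec$residual, converged = dec$converged,
            meta = list(n = P$n, nt = P$N_T),
            extra = list(projected = list(L = dec$L, S = dec$S),
                         invertible = TRUE, projection = P))
  } else {
    new_pcp(L = unclass_matrix(dec$L), S = unclass_matrix(dec$S),
            lam = dec$lam, iterations = dec$iterations,
            residual = dec$residual, converged = dec$converged,
            meta = list(n = P$m, nt = P$N_T),
            extra = list(projected = list(L = dec$L, S = dec$S),
                         invertible = FALSE, projection = P))
  }
}
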
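#' Stacked trial-by-(species x time) data matrix
#'
#' The central container: a numeric matrix with `q` rows (trials,
#' perturbation experiments, cell lines) and `n * N_T` columns laid out
#' species-major -- columns `(i-1)*N_T + 1 .. i*N_T` hold the full time
#' course of species `i`, in temporal order.  This block layout is what
#' the Kronecker projection operator `t(Psi) %x% I_NT` acts on: it mixes
#' species blocks but never mixes time points within a block.
#'
#' @param values numeric matrix, `q` by `n * N_T`, all entries finite.
#' @param n_species number of species (neurons, genes, proteins) `n`.
#' @param n_timepoints number of time points per species block `N_T`.
#' @param row_labels,column_labels optional character labels; defaults are
#'   generated (`trial_1, ...` and `s<i>_t<j>`).
#' @return a `data_matrix`: a numeric matrix carrying `n_species` and
#'   `n_timepoints` attributes.
#' @examples
#' X <- data_matrix(matrix(1:12, 2, 6), n_species = 2, n_timepoints = 3)
#' species_block(X, 2)
#' @export
data_matrix <- function(values, n_species, n_timepoints,
                        row_labels = NULL, column_labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n_species <- as.integer(n_species)
  n_timepoints <- as.integer(n_timepoints)
  if (n_species < 1L || n_timepoints < 1L)
    stop("n_species and n_timepoints must be positive", call. = FALSE)
  if (ncol(values) != n_species * n_timepoints)
    stop(sprintf("column count (%d) must equal n_species * n_timepoints (%d x %d = %d)",
                 ncol(values), n_species, n_timepoints,
                 n_species * n_timepoints), call. = FALSE)
  if (!all(is.finite(values)))
    stop("all entries of a data_matrix must be finite", call. = FALSE)
  if (is.null(row_labels))
    row_labels <- rownames(values) %||% paste0("trial_", seq_len(nrow(values)))
  if (is.null(column_labels))
    column_labels <- colnames(values) %||%
      paste0("s", rep(seq_len(n_species), each = n_timepoints),
             "_t", rep(seq_len(n_timepoints), n_species))
  dimnames(values) <- list(row_labels, column_labels)
  structure(values, n_species = n_species, n_timepoints = n_timepoints,
            class = c("data_matrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("data_matrix: %d trials x (%d species x %d time points)\n",
              nrow(x), n_species(x), n_timepoints(x)))
  print(unclass_matrix(x)[seq_len(min(6L, nrow(x))),
                          seq_len(min(8L, ncol(x))), drop = FALSE], ...)
  if (nrow(x) > 6L || ncol(x) > 8L) cat("...\n")
  invisible(x)
}

unclass_matrix <- function(x) {
  attr(x, "n_species") <- NULL
  attr(x, "n_timepoints") <- NULL
  class(x) <- NULL
  x
}

#' @rdname data_matrix
#' @param X a `data_matrix` (or plain matrix where stated).
#' @export
n_species <- function(X) {
  v <- attr(X, "n_species")
  if (is.null(v)) stop("not a data_matrix: missing n_species metadata", call. = FALSE)
  v
}

#' @rdname data_matrix
#' @export
n_timepoints <- function(X) {
  v <- attr(X, "n_timepoints")
  if (is.null(v)) stop("not a data_matrix: missing n_timepoints metadata", call. = FALSE)
  v
}

#' @rdname data_matrix
#' @param i species index.
#' @export
species_block <- function(X, i) {
  nt <- n_timepoints(X)
  i <- as.integer(i)
  if (i < 1L || i > n_species(X)) stop("species index out of range", call. = FALSE)
  unclass_matrix(X)[, (i - 1L) * nt + seq_len(nt), drop = FALSE]
}

# Coerce plain-matrix input (plus explicit n/N_T) to data_matrix, or pass
# a data_matrix through; used by functions that accept either.
as_data_matrix <- function(X, n_species = NULL, n_timepoints = NULL) {
  if (inherits(X, "data_matrix")) return(X)
  if (is.null(n_species) || is.null(n_timepoints))
    stop("plain matrix input needs n_species and n_timepoints", call. = FALSE)
  data_matrix(X, n_species, n_timepoints)
}

# Reshape the q x (n*N_T) species-major matrix to a (q*N_T) x n matrix
# whose columns are species; inverse of fold_species. This is the cheap
# route for block-wise application of species-mixing operators.
unfold_species <- function(X) {
  q <- nrow(X); n <- n_species(X); nt <- n_timepoints(X)
  dim_saved <- c(q, nt, n)
  m <- unclass_matrix(X)
  dim(m) <- dim_saved          # columns vary time fastest within species
  matrix(m, q * nt, n)
}

fold_species <- function(M2, q, n_timepoints, row_labels = NULL) {
  n <- ncol(M2)
  out <- matrix(as.vector(M2), q, n * n_timepoints)
  data_matrix(out, n, n_timepoints, row_labels = row_labels)
}
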
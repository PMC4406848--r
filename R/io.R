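#' Read and write data matrices with block metadata
#'
#' A `data_matrix` on disk is a delimited table of values plus a one-line
#' JSON sidecar (`<path>.json`) carrying the block-layout metadata
#' (`q`, `n`, `N_T`, `block_order`, labels), so a file is always
#' self-describing and a decomposition can be replayed from disk exactly.
#' Values round-trip through text at 17 significant digits (lossless for
#' doubles); `format = "rds"` stores the object natively for a bit-exact
#' binary round trip.
#'
#' @param X a [data_matrix()].
#' @param path output file path; the sidecar goes to `<path>.json`.
#' @param format `"csv"`, `"tsv"` or `"rds"`.
#' @return `write_data_matrix` returns `path` invisibly;
#'   `read_data_matrix` returns a [data_matrix()].
#' @export
write_data_matrix <- function(X, path, format = c("csv", "tsv", "rds")) {
  format <- match.arg(format)
  stopifnot(inherits(X, "data_matrix"))
  if (format == "rds") {
    saveRDS(X, path)
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  m <- unclass_matrix(X)
  tab <- as.data.frame(format(m, digits = 17, scientific = TRUE, trim = TRUE))
  names(tab) <- colnames(m)
  write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  meta <- list(q = nrow(X), n = n_species(X), N_T = n_timepoints(X),
               block_order = "species_major",
               row_labels = rownames(X), column_labels = colnames(X))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_data_matrix
#' @export
read_data_matrix <- function(path, format = c("csv", "tsv", "rds")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "rds") return(readRDS(path))
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing metadata sidecar ", side,
         " (write with write_data_matrix, or create the JSON with fields q, n, N_T)",
         call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  sep <- if (format == "csv") "," else "\t"
  tab <- read.csv(path, sep = sep, check.names = FALSE)
  m <- as.matrix(tab)
  if (ncol(m) != meta$n * meta$N_T)
    stop(sprintf("file has %d columns but sidecar declares n*N_T = %d; regenerate the sidecar",
                 ncol(m), meta$n * meta$N_T), call. = FALSE)
  data_matrix(m, meta$n, meta$N_T, row_labels = meta$row_labels,
              column_labels = meta$column_labels)
}

#' Serialize a decomposition to disk
#'
#' Writes `L` and `S` as two matrix files (with their sidecars) plus a
#' JSON diagnostics record (`lam`, `iterations`, `residual`, `converged`,
#' rank of `L`).
#'
#' @param decomposition a `pcp_decomposition` whose `L`/`S` carry block
#'   metadata.
#' @param dir output directory (created if needed).
#' @param format matrix format, `"csv"` or `"tsv"`.
#' @return `write_decomposition` returns `dir` invisibly;
#'   `read_decomposition` returns a `pcp_decomposition`.
#' @export
write_decomposition <- function(decomposition, dir, format = c("csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(decomposition, "pcp_decomposition"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_data_matrix(decomposition$L, file.path(dir, paste0("L.", format)), format)
  write_data_matrix(decomposition$S, file.path(dir, paste0("S.", format)), format)
  diag_rec <- list(lam = decomposition$lam,
                   iterations = decomposition$iterations,
                   residual = decomposition$residual,
                   converged = decomposition$converged,
                   rank_L = numerical_rank(decomposition$L),
                   invertible = decomposition$invertible)
  jsonlite::write_json(diag_rec, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(dir, format = c("csv", "tsv")) {
  format <- match.arg(format)
  L <- read_data_matrix(file.path(dir, paste0("L.", format)), format)
  S <- read_data_matrix(file.path(dir, paste0("S.", format)), format)
  d <- jsonlite::read_json(file.path(dir, "diagnostics.json"), simplifyVector = TRUE)
  new_pcp(L = unclass_matrix(L), S = unclass_matrix(S), lam = d$lam,
          iterations = d$iterations, residual = d$residual,
          converged = d$converged,
          meta = list(n = n_species(L), nt = n_timepoints(L)))
}

#' Serialize a projection operator
#'
#' The `Psi` matrix as CSV plus JSON metadata (`m`, `n`, `N_T`, `seed`,
#' `distribution`), so a projected decomposition is exactly replayable.
#'
#' @param P a [make_projection()] operator.
#' @param path base path; writes `<path>.csv` and `<path>.json`.
#' @return `write_projection` returns `path` invisibly;
#'   `read_projection` returns the operator.
#' @export
write_projection <- function(P, path) {
  stopifnot(inherits(P, "projection_operator"))
  write.table(format(P$psi, digits = 17, scientific = TRUE, trim = TRUE),
              paste0(path, ".csv"), sep = ",", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(P[c("m", "n", "N_T", "seed", "distribution")],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_projection
#' @export
read_projection <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  psi <- as.matrix(read.csv(paste0(path, ".csv"), header = FALSE))
  dimnames(psi) <- NULL
  storage.mode(psi) <- "double"
  structure(list(psi = psi, m = meta$m, n = meta$n, N_T = meta$N_T,
                 seed = meta$seed, distribution = meta$distribution),
            class = "projection_operator")
}
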
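#' Trial tensor: aligned multi-trial spatio-temporal recordings
#'
#' A `q x n x N_T` array of `q` trials (or perturbation experiments),
#' each an `n`-species by `N_T`-time-point recording, already aligned on
#' a common within-trial event (e.g. submovement onset).  This is the
#' raw input that [build_data_matrix()] flattens into the stacked
#' trial-by-(species x time) matrix.
#'
#' @param data numeric array `q x n x N_T`.
#' @param trial_labels,species_labels optional character labels.
#' @param time_labels optional numeric time stamps, strictly increasing;
#'   default `0:(N_T-1)`.
#' @param alignment_index within-trial sample index (1-based) the trials
#'   are aligned on; purely annotative.
#' @return a `trial_tensor`.
#' @export
trial_tensor <- function(data, trial_labels = NULL, species_labels = NULL,
                         time_labels = NULL, alignment_index = NA_integer_) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("trial tensor must be a 3-d array (trials x species x time)", call. = FALSE)
  storage.mode(data) <- "double"
  d <- dim(data)
  trial_labels <- trial_labels %||% paste0("trial_", seq_len(d[1]))
  species_labels <- species_labels %||% paste0("s", seq_len(d[2]))
  time_labels <- time_labels %||% as.numeric(seq_len(d[3]) - 1L)
  if (length(time_labels) != d[3] || any(diff(time_labels) <= 0))
    stop("time_labels must be strictly increasing and match the time dimension",
         call. = FALSE)
  dimnames(data) <- list(trial_labels, species_labels, NULL)
  structure(list(data = data, trial_labels = trial_labels,
                 species_labels = species_labels,
                 time_labels = as.numeric(time_labels),
                 alignment_index = alignment_index),
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("trial_tensor: %d trials x %d species x %d time points\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' @export
dim.trial_tensor <- function(x) dim(x$data)

#' Stack a trial tensor into a data matrix
#'
#' Row `i` of the result is the species-major vectorization of trial `i`:
#' columns are grouped per species, `N_T` consecutive time points each.
#' This layout is what the Kronecker projection operator acts on.
#'
#' @param tt a [trial_tensor()].
#' @return a [data_matrix()] of shape `q` by `n * N_T`.
#' @examples
#' tt <- trial_tensor(array(1:8, c(2, 2, 2)))
#' build_data_matrix(tt)
#' @export
build_data_matrix <- function(tt) {
  stopifnot(inherits(tt, "trial_tensor"))
  d <- dim(tt$data)
  flat <- matrix(aperm(tt$data, c(1, 3, 2)), d[1], d[2] * d[3])
  data_matrix(flat, n_species = d[2], n_timepoints = d[3],
              row_labels = tt$trial_labels,
              column_labels = paste0(rep(tt$species_labels, each = d[3]),
                                     "_t", rep(seq_len(d[3]), d[2])))
}

#' Unstack a data matrix back into a trial tensor
#'
#' Exact inverse of [build_data_matrix()]: `unbuild_data_matrix(build_data_matrix(tt))`
#' reproduces `tt`'s array.  Needed to render per-species heat maps of
#' recovered `L` / `S` components.
#'
#' @param X a [data_matrix()] (block metadata required).
#' @param species_labels,time_labels optional labels for the rebuilt tensor.
#' @return a [trial_tensor()].
#' @export
unbuild_data_matrix <- function(X, species_labels = NULL, time_labels = NULL) {
  n <- n_species(X); nt <- n_timepoints(X); q <- nrow(X)
  arr <- array(unclass_matrix(X), c(q, nt, n))
  trial_tensor(aperm(arr, c(1, 3, 2)),
               trial_labels = rownames(X),
               species_labels = species_labels,
               time_labels = time_labels)
}

#' Align ragged trials on a per-trial event
#'
#' Extracts an equal-length window around each trial's event index so the
#' trials can be stacked: the window covers samples
#' `[onset - pre, onset + post)` in 0-based sample indices, giving
#' `N_T = pre + post` points with the event at position `pre` (0-based)
#' within the window.  Trials whose recording is too short to cover the
#' window are dropped, with a message reporting the count.
#'
#' @param raw list of numeric matrices, one per trial, each `n` species by
#'   `T_i` samples (ragged `T_i` allowed).  Vectors are treated as
#'   single-species recordings.
#' @param onsets integer vector of 0-based per-trial event sample indices.
#' @param window length-2 integer vector `c(pre, post)`: samples kept
#'   before and after (event sample included in `post`).
#' @return a [trial_tensor()] with `N_T = pre + post` and
#'   `alignment_index = pre + 1` (1-based position of the event).
#' @examples
#' raw <- list(matrix(1:10, 1), matrix(101:112, 1))
#' align_trials(raw, onsets = c(5, 3), window = c(2, 3))
#' @export
align_trials <- function(raw, onsets, window) {
  stopifnot(is.list(raw), length(raw) == length(onsets), length(window) == 2L)
  pre <- as.integer(window[1]); post <- as.integer(window[2])
  if (pre < 0L || post < 1L) stop("window must have pre >= 0, post >= 1", call. = FALSE)
  raw <- lapply(raw, function(x) if (is.matrix(x)) x else matrix(x, nrow = 1))
  ns <- vapply(raw, nrow, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all trials must record the same species", call. = FALSE)
  n <- ns[1]; nt <- pre + post
  keep <- logical(length(raw))
  segs <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    start0 <- onsets[i] - pre              # 0-based, inclusive
    end0 <- onsets[i] + post               # 0-based, exclusive
    if (start0 >= 0 && end0 <= ncol(raw[[i]])) {
      keep[i] <- TRUE
      segs[[i]] <- raw[[i]][, (start0 + 1L):end0, drop = FALSE]
    }
  }
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("align_trials: dropped %d trial(s) too short for the window", dropped))
  if (!any(keep)) stop("no trial covers the requested window", call. = FALSE)
  arr <- array(0, c(sum(keep), n, nt))
  for (j in seq_along(which(keep))) arr[j, , ] <- segs[[which(keep)[j]]]
  trial_tensor(arr, trial_labels = paste0("trial_", which(keep)),
               alignment_index = pre + 1L)
}
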
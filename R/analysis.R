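#' Extract a detection template from a low-rank component
#'
#' Summarizes the common response `L` as a single species-major feature
#' vector of length `n * N_T`, to be slid along a test stream by
#' [correlation_score()].  The default is the leading right singular
#' vector of `L` (unit norm, sign fixed so its largest-magnitude entry is
#' positive) -- the rank-1 summary of the common response; `"rowmean"`
#' returns the mean row instead.
#'
#' @param L numeric matrix (typically the `L` of a decomposition).
#' @param method `"svd"` (default) or `"rowmean"`.
#' @return numeric template vector of length `ncol(L)`.
#' @export
extract_template <- function(L, method = c("svd", "rowmean")) {
  method <- match.arg(method)
  L <- if (inherits(L, "data_matrix")) unclass_matrix(L) else as.matrix(L)
  if (all(L == 0)) stop("cannot extract a template from a zero matrix", call. = FALSE)
  if (method == "rowmean") return(colMeans(L))
  v <- svd(L, nu = 0, nv = 1)$v[, 1]
  s <- sign(v[which.max(abs(v))])
  if (s < 0) v <- -v
  v
}

#' Sliding-window correlation score against a template
#'
#' Slides a species-major window of `N_T = length(template) / n` time
#' points along a continuous `n`-species stream and reports the Pearson
#' correlation between each vectorized window and the template -- the
#' event-detection score trace.  Windows with zero variance score 0 (the
#' count is attached as attribute `n_degenerate`).
#'
#' @param signal numeric matrix, `n` species by `T` samples (`T >=` the
#'   window length); a vector is treated as one species.
#' @param template species-major template, length divisible by `n`.
#' @param stride window-start step in samples; default 1.
#' @return numeric score vector, one entry per window start (attribute
#'   `starts` holds the 1-based start indices).
#' @export
correlation_score <- function(signal, template, stride = 1L) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1)
  n <- nrow(signal)
  if (length(template) %% n != 0)
    stop("template length must be a multiple of the species count", call. = FALSE)
  nt <- length(template) %/% n
  Tlen <- ncol(signal)
  if (Tlen < nt) stop("stream shorter than the template window", call. = FALSE)
  starts <- seq(1L, Tlen - nt + 1L, by = as.integer(stride))
  degenerate <- 0L
  scores <- vapply(starts, function(s) {
    w <- as.vector(t(signal[, s:(s + nt - 1L), drop = FALSE]))  # species-major
    if (sd(w) == 0 || sd(template) == 0) {
      degenerate <<- degenerate + 1L
      return(0)
    }
    cor(w, template)
  }, numeric(1))
  if (degenerate > 0)
    message(sprintf("correlation_score: %d zero-variance window(s) scored 0", degenerate))
  structure(scores, starts = starts, n_degenerate = degenerate)
}

#' ROC curve for threshold-crossing event detection
#'
#' For each threshold, detection *events* are the rising-edge crossings of
#' the score trace, so a sustained excursion raises one false alarm, not
#' many.  A true onset counts as hit (TP) when any above-threshold window
#' start lies within `match_window` samples of it; a detection event
#' matched to no onset is a false positive.  The false-positive rate is
#' normalized by the number of eligible negative window starts -- those
#' farther than `match_window` from every true onset.  A threshold below
#' the whole trace therefore gives TPR 1, and one above it gives
#' (FPR, TPR) = (0, 0).
#'
#' @param scores score trace from [correlation_score()].
#' @param true_onsets 1-based window-start indices of the true events.
#' @param thresholds numeric vector of score cutoffs.
#' @param match_window tolerance in samples for counting a hit; default 5.
#' @return data frame with columns `threshold`, `fpr`, `tpr`,
#'   `n_detected`, sorted by threshold.
#' @export
roc_curve <- function(scores, true_onsets, thresholds, match_window = 5L) {
  if (length(true_onsets) == 0) stop("no true onsets supplied", call. = FALSE)
  if (length(thresholds) == 0) stop("thresholds must be nonempty", call. = FALSE)
  starts <- attr(scores, "starts") %||% seq_along(scores)
  scores <- as.numeric(scores)
  dist_to_onset <- vapply(starts, function(s) min(abs(s - true_onsets)), numeric(1))
  n_negative <- sum(dist_to_onset > match_window)
  rows <- lapply(sort(thresholds), function(th) {
    above <- starts[scores >= th]
    cross <- scores >= th & c(TRUE, scores[-length(scores)] < th)
    det <- starts[cross]
    tp <- sum(vapply(true_onsets,
                     function(o) any(abs(above - o) <= match_window), logical(1)))
    fp <- if (length(det) == 0) 0L else
      sum(vapply(det, function(d) all(abs(d - true_onsets) > match_window),
                 logical(1)))
    data.frame(threshold = th,
               fpr = if (n_negative > 0) fp / n_negative else 0,
               tpr = tp / length(true_onsets),
               n_detected = length(det))
  })
  do.call(rbind, rows)
}

#' Area under an ROC curve
#'
#' Trapezoidal area under the (FPR, TPR) points of [roc_curve()],
#' anchored at (0, 0) and (1, 1).
#'
#' @param roc data frame with `fpr` and `tpr` columns.
#' @return scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  fpr <- c(0, sort(roc$fpr), 1)
  tpr <- c(0, roc$tpr[order(roc$fpr)], 1)
  tpr <- cummax(tpr)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

safe_row_cor <- function(A) {
  # Pearson correlation between rows; zero-variance rows get correlation 0
  # with everything (distance 1), matching the convention for flat trials.
  v <- apply(A, 1, sd)
  C <- matrix(0, nrow(A), nrow(A))
  ok <- v > 0
  if (sum(ok) >= 2) C[ok, ok] <- cor(t(A[ok, , drop = FALSE]))
  diag(C) <- 1
  list(C = C, n_flat = sum(!ok))
}

#' Correlation dissimilarity between raw trials
#'
#' `d_xy(i, j) = 1 - cor(X[i, ], X[j, ])`, the 1-correlation distance on
#' raw rows.  Being affine-invariant per row, it removes trial-to-trial
#' shifts in measurement level and range.  Zero-variance rows are at
#' distance 1 from everything (reported via a message).
#'
#' @param X a [data_matrix()] or plain matrix, trials in rows.
#' @return a `dissimilarity_matrix`: symmetric `q x q` matrix in
#'   `[0, 2]` with zero diagonal, attribute `measure = "raw"`.
#' @export
dissimilarity_raw <- function(X) {
  Xm <- if (inherits(X, "data_matrix")) unclass_matrix(X) else as.matrix(X)
  rc <- safe_row_cor(Xm)
  if (rc$n_flat > 0)
    message(sprintf("dissimilarity_raw: %d zero-variance row(s) at distance 1 from all others",
                    rc$n_flat))
  D <- 1 - rc$C
  diag(D) <- 0
  structure(D, measure = "raw", gamma = NA_real_,
            class = c("dissimilarity_matrix", "matrix", "array"))
}

#' Disentangled correlation dissimilarity on (L, S)
#'
#' Distance between trials computed on the decomposition instead of the
#' raw rows: a convex combination of the 1-correlation distances of the
#' common components and of the aberrant components,
#' `d(i, j) = (1 - gamma) * (1 - cor(L_i, L_j)) + gamma * (1 - cor(S_i, S_j))`.
#' `gamma` weights the aberrant part: 0 compares common responses only,
#' 1 compares aberrations only.  All-zero rows of `S` (trials with no
#' aberration) contribute a sparse term of 0 between two such trials and
#' 1 against a trial that does have aberrations.
#'
#' @param decomposition a `pcp_decomposition` (row-aligned `L` and `S`).
#' @param gamma weight of the sparse term in `[0, 1]`; default 0.5.
#' @return a `dissimilarity_matrix` with attributes `measure =
#'   "disentangled"` and `gamma`.
#' @export
dissimilarity_disentangled <- function(decomposition, gamma = 0.5) {
  stopifnot(inherits(decomposition, "pcp_decomposition"))
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]", call. = FALSE)
  L <- decomposition$L; S <- decomposition$S
  L <- if (inherits(L, "data_matrix")) unclass_matrix(L) else as.matrix(L)
  S <- if (inherits(S, "data_matrix")) unclass_matrix(S) else as.matrix(S)
  if (!identical(dim(L), dim(S)))
    stop("L and S must share shape", call. = FALSE)
  dL <- 1 - safe_row_cor(L)$C
  zero_row <- rowSums(S != 0) == 0
  dS <- 1 - safe_row_cor(S)$C
  # a trial with no aberration has no sparse term to compare: against
  # another aberration-free trial the pair is judged on L alone (full
  # weight, so S = 0 everywhere reduces to the raw distance on L); against
  # an aberrant trial the sparse term is maximal
  dS[zero_row, ] <- 1
  dS[, zero_row] <- 1
  D <- (1 - gamma) * dL + gamma * dS
  D[zero_row, zero_row] <- dL[zero_row, zero_row]
  diag(D) <- 0
  structure(D, measure = "disentangled", gamma = gamma,
            class = c("dissimilarity_matrix", "matrix", "array"))
}

#' Agglomerative clustering of a dissimilarity matrix
#'
#' Standard hierarchical clustering ([stats::hclust()]) on the given
#' dissimilarity, cut at `k` clusters.
#'
#' @param D a `dissimilarity_matrix` (or any symmetric distance matrix).
#' @param k number of clusters, `1 <= k <= nrow(D)`.
#' @param linkage linkage method passed to [stats::hclust()]; default
#'   `"average"`.
#' @return integer cluster labels, one per row of `D`; the `hclust` tree
#'   is attached as attribute `tree`.
#' @export
hierarchical_cluster <- function(D, k, linkage = "average") {
  Dm <- unclass(D); attr(Dm, "measure") <- NULL; attr(Dm, "gamma") <- NULL
  if (k < 1 || k > nrow(Dm))
    stop("k must be between 1 and the number of rows", call. = FALSE)
  if (nrow(Dm) == 1L) return(structure(1L, tree = NULL))
  tree <- hclust(as.dist(Dm), method = linkage)
  structure(cutree(tree, k = k), tree = tree)
}
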
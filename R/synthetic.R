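#' Generate a sparse low-rank data matrix
#'
#' Builds `X = U %*% t(V)` from sparse random-sign factors: `U` (`q x r`)
#' and `V` (`n*N_T x r`) have i.i.d. unit-magnitude random-sign entries
#' masked so that each column keeps a `factor_sparsity` fraction of
#' nonzeros.  The product is both exactly rank `r` (regenerated from a
#' fresh sub-seed until [numerical_rank()] confirms it) and sparse,
#' mimicking inputs -- few active neurons, sparsely perturbed networks --
#' whose sparsity breaks plain PCP identifiability.  Unit-magnitude
#' factors keep the nonzero entries of `X` homogeneous in scale; with
#' heavy-tailed (e.g. Gaussian-product) entries the few largest entries
#' of `X` are cheaper to park in the sparse component than to cover with
#' nuclear norm, and PCP shreds the signal itself at any useful lambda
#' instead of exhibiting the sparse-input identifiability failure this
#' benchmark is meant to probe (`factor_law = "gaussian"` is available
#' for that regime).  Defaults reproduce the benchmark instance: 50
#' trials of 2 species over 10 time points at rank 6.
#'
#' @param q,n,N_T matrix dimensions (trials, species, time points).
#' @param rank target rank, at most `min(q, n*N_T)`; `rank = 0` gives the
#'   zero matrix.
#' @param factor_sparsity fraction of nonzeros kept per factor column,
#'   in (0, 1]; default 0.3.
#' @param factor_law `"rademacher"` (default, unit-magnitude random
#'   signs) or `"gaussian"` for the nonzero factor entries.
#' @param seed integer seed; output is deterministic given the seed.
#' @return a [data_matrix()] with `numerical_rank(X) == rank`.
#' @examples
#' X <- gen_sparse_lowrank(seed = 1)
#' numerical_rank(X)
#' @export
gen_sparse_lowrank <- function(q = 50, n = 2, N_T = 10, rank = 6,
                               factor_sparsity = 0.3,
                               factor_law = c("rademacher", "gaussian"),
                               seed = 0L) {
  factor_law <- match.arg(factor_law)
  q <- as.integer(q); n <- as.integer(n); N_T <- as.integer(N_T)
  p <- n * N_T
  if (q < 1L || n < 1L || N_T < 1L) stop("dimensions must be positive", call. = FALSE)
  if (rank < 0 || rank > min(q, p))
    stop("rank must satisfy 0 <= rank <= min(q, n*N_T)", call. = FALSE)
  if (factor_sparsity <= 0 || factor_sparsity > 1)
    stop("factor_sparsity must be in (0, 1]", call. = FALSE)
  if (rank == 0L)
    return(data_matrix(matrix(0, q, p), n, N_T))
  ku <- max(1L, ceiling(factor_sparsity * q))
  kv <- max(1L, ceiling(factor_sparsity * p))
  draw <- function(k) {
    if (factor_law == "rademacher") sample(c(-1, 1), k, replace = TRUE)
    else rnorm(k)
  }
  for (attempt in 0:99) {
    X <- with_seed(split_seed(seed, "sparse_lowrank", attempt), {
      U <- matrix(draw(q * rank), q, rank)
      V <- matrix(draw(p * rank), p, rank)
      for (j in seq_len(rank)) {
        U[-sample.int(q, ku), j] <- 0
        V[-sample.int(p, kv), j] <- 0
      }
      U %*% t(V)
    })
    if (numerical_rank(X) == rank)
      return(data_matrix(X, n, N_T))
  }
  stop(sprintf("could not realize rank %d in 100 attempts", rank), call. = FALSE)
}

#' Add sparse corruption to a data matrix
#'
#' Corrupts exactly `floor(rho * q * n * N_T)` entries, chosen uniformly
#' without replacement, by adding `+/- amplitude * RMS(X)` with random
#' signs.  Both the corrupted matrix and the corruption itself are
#' returned, so recovery of the sparse component can be scored against
#' the truth.
#'
#' The default amplitude (`NULL`) is norm-matched: it is set to
#' `sqrt(length(X) / k)` (about `1/sqrt(rho)`) so that the Frobenius
#' norm of the corruption equals that of the signal,
#' `||S_corruption||_F = ||X||_F` -- a corruption comparable to the
#' signal rather than buried under it.  A fixed multiple of the RMS can
#' be requested explicitly (e.g. `amplitude = 1`).
#'
#' @param X a [data_matrix()] (or plain matrix).
#' @param rho fraction of corrupted entries, in `[0, 1)`; default 0.05.
#' @param amplitude corruption scale relative to the root-mean-square of
#'   `X`; default `NULL` = norm-matched (see Details).
#' @param seed integer seed.
#' @return list with `corrupted` (same class as `X`) and `corruption`
#'   (plain matrix, `X + corruption == corrupted` elementwise).
#' @export
add_sparse_corruption <- function(X, rho = 0.05, amplitude = NULL, seed = 0L) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  if (!is.null(amplitude) && amplitude <= 0)
    stop("amplitude must be positive", call. = FALSE)
  Xm <- if (inherits(X, "data_matrix")) unclass_matrix(X) else as.matrix(X)
  k <- floor(rho * length(Xm))
  if (is.null(amplitude)) amplitude <- if (k > 0) sqrt(length(Xm) / k) else 1
  S <- array(0, dim(Xm))
  if (k > 0) {
    rms <- sqrt(mean(Xm^2))
    S[] <- with_seed(split_seed(seed, "corruption"), {
      out <- numeric(length(Xm))
      idx <- sample.int(length(Xm), k)
      out[idx] <- sample(c(-1, 1), k, replace = TRUE) * amplitude * rms
      out
    })
  }
  corrupted <- Xm + S
  if (inherits(X, "data_matrix"))
    corrupted <- data_matrix(corrupted, n_species(X), n_timepoints(X),
                             row_labels = rownames(X))
  list(corrupted = corrupted, corruption = S)
}

#' Generate sparse, eccentric spike-rate trial tensors
#'
#' Emulates trial-aligned population spiking: only an `active_fraction`
#' of neurons fires at all, and mean rates are heavy-tailed -- a few
#' neurons at the top of `rate_range` (tens of spikes/s) while most emit
#' only a few.  `eccentricity` sets the ratio of the top-decile to the
#' median mean rate (log-normal rate law).  Each trial's temporal profile
#' is a nonnegative combination of `template_rank` shared smooth bumps,
#' so the noiseless panel is low-rank; with `noise = TRUE` rates are
#' passed through Poisson spike-count binning at `bin_width` seconds and
#' converted back to rates, clipped at the top of `rate_range`.
#'
#' @param q,n,N_T trials, neurons, time bins.
#' @param active_fraction fraction of neurons active, in (0, 1].
#' @param rate_range numeric length 2, firing-rate range in spikes/s
#'   (within `[0, 40]`).
#' @param eccentricity ratio of top-decile to median mean rate, `>= 1`.
#' @param template_rank number of shared temporal templates.
#' @param noise add Poisson binning noise? default `TRUE`.
#' @param bin_width bin width in seconds for the Poisson counts.
#' @param seed integer seed.
#' @return a [trial_tensor()] of nonnegative rates, all `<= max(rate_range)`.
#' @export
gen_neural_trials <- function(q = 50, n = 64, N_T = 20, active_fraction = 0.3,
                              rate_range = c(1, 40), eccentricity = 10,
                              template_rank = 2, noise = TRUE,
                              bin_width = 0.05, seed = 0L) {
  if (active_fraction <= 0 || active_fraction > 1)
    stop("active_fraction must be in (0, 1]", call. = FALSE)
  if (min(rate_range) < 0 || max(rate_range) > 40)
    stop("rate_range must lie within [0, 40] spikes/s", call. = FALSE)
  if (eccentricity < 1) stop("eccentricity must be >= 1", call. = FALSE)
  r_max <- max(rate_range); r_min <- min(rate_range)
  arr <- with_seed(split_seed(seed, "neural_trials"), {
    # log-normal mean rates: eccentricity = q90/median = exp(sigma * z90)
    sdlog <- log(eccentricity) / qnorm(0.9)
    raw_rates <- exp(rnorm(n, sd = sdlog))
    rates <- pmax(r_min, r_max * raw_rates / max(raw_rates))
    active <- runif(n) < active_fraction
    # shared smooth temporal templates (Gaussian bumps), nonneg coefficients
    t_grid <- seq_len(N_T)
    centers <- runif(template_rank, 1, N_T)
    widths <- runif(template_rank, N_T / 8, N_T / 3)
    Tmp <- sapply(seq_len(template_rank),
                  function(k) exp(-(t_grid - centers[k])^2 / (2 * widths[k]^2)))
    Tmp <- matrix(Tmp, N_T, template_rank)
    coef <- matrix(abs(rnorm(q * template_rank)), q, template_rank)
    prof <- coef %*% t(Tmp)                      # q x N_T, nonnegative
    prof <- prof / pmax(apply(prof, 1, max), .Machine$double.eps)
    arr <- array(0, c(q, n, N_T))
    for (s in seq_len(n)) {
      if (!active[s]) next
      lam_rates <- rates[s] * prof               # q x N_T
      if (noise) {
        counts <- matrix(rpois(q * N_T, lam_rates * bin_width), q, N_T)
        arr[, s, ] <- pmin(counts / bin_width, r_max)
      } else {
        arr[, s, ] <- lam_rates
      }
    }
    arr
  })
  trial_tensor(arr)
}

#' Linear perturbation-response network model
#'
#' A wild-type dynamical system `dx/dt = A x` plus a panel of sparse
#' perturbations, each adding a constant forcing to exactly one species'
#' equation from its onset time onward (small-molecule inhibitors and
#' point mutations act on a single target, though their influence
#' propagates through the network over time).
#'
#' @param A `n x n` interaction matrix (linearized wild-type field).
#' @param perturbations list of perturbations, each a list with `target`
#'   (species index), `effect` (positive magnitude), `sign` (+1 or -1,
#'   default -1 for inhibition) and `onset` (time, default 0).
#' @param x0 initial state, length `n`.
#' @param dt integration step (also the sampling interval).
#' @param N_T number of samples (grid `0, dt, ..., (N_T-1)*dt`).
#' @return a `network_model`.
#' @export
network_model <- function(A, perturbations = list(), x0 = NULL,
                          dt = 0.1, N_T = 20) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("A must be square", call. = FALSE)
  n <- nrow(A)
  x0 <- x0 %||% rep(1, n)
  if (length(x0) != n) stop("x0 must have length n", call. = FALSE)
  for (p in perturbations) {
    if (is.null(p$target) || length(p$target) != 1L || p$target < 1 || p$target > n)
      stop("each perturbation must target exactly one species", call. = FALSE)
  }
  structure(list(A = A, perturbations = perturbations, x0 = as.numeric(x0),
                 dt = dt, N_T = as.integer(N_T), n = n),
            class = "network_model")
}

#' Simulate a wild-type + perturbation response panel
#'
#' Integrates the model with fixed-step fourth-order Runge-Kutta on the
#' sampling grid.  Row 1 of the resulting tensor is the unperturbed
#' wild-type trajectory; each following row adds one perturbation's
#' forcing term.  `A` must be stable (all eigenvalue real parts
#' negative) unless `check_stability = FALSE`.
#'
#' @param model a [network_model()].
#' @param check_stability refuse unstable `A`? default `TRUE`.
#' @return a [trial_tensor()] with `1 + length(perturbations)` trials,
#'   labelled `wild_type`, `pert_1`, ...
#' @export
simulate_perturbation_panel <- function(model, check_stability = TRUE) {
  stopifnot(inherits(model, "network_model"))
  if (check_stability && max(Re(eigen(model$A, only.values = TRUE)$values)) >= 0)
    stop("A is not stable (spectral abscissa >= 0); pass check_stability = FALSE to override",
         call. = FALSE)
  times <- (seq_len(model$N_T) - 1L) * model$dt
  integrate_one <- function(pert) {
    rhs <- function(t, x, parms) {
      dx <- as.vector(model$A %*% x)
      if (!is.null(pert) && t >= (pert$onset %||% 0)) {
        sgn <- pert$sign %||% -1
        dx[pert$target] <- dx[pert$target] + sgn * pert$effect
      }
      list(dx)
    }
    out <- deSolve::ode(y = model$x0, times = times, func = rhs,
                        parms = NULL, method = "rk4")
    t(out[, -1, drop = FALSE])                    # n x N_T
  }
  q <- 1L + length(model$perturbations)
  arr <- array(0, c(q, model$n, model$N_T))
  arr[1, , ] <- integrate_one(NULL)
  for (j in seq_along(model$perturbations))
    arr[j + 1L, , ] <- integrate_one(model$perturbations[[j]])
  trial_tensor(arr,
               trial_labels = c("wild_type",
                                paste0("pert_", seq_along(model$perturbations),
                                       recycle0 = TRUE)),
               time_labels = times)
}

#' Generate a trial panel with a common template plus aberrant trials
#'
#' Emulates trial-aligned recordings used for event detection: every
#' trial carries a shared species-by-time response pattern (a smooth
#' bump per species, scaled by a per-trial amplitude), while a fraction
#' of trials are aberrant -- their rows are dominated by large
#' task-irrelevant activity.  Aberrant rows stay row-sparse under
#' species mixing, which is what lets the projected decomposition peel
#' them off and recover a clean detection template.
#'
#' @param q trials; @param n species; @param N_T time points.
#' @param n_aberrant number of aberrant trials.
#' @param aberrant_amp amplitude of aberrant activity relative to the
#'   pattern's peak; default 5.
#' @param seed integer seed.
#' @return list with `X` (the [data_matrix()]), `pattern` (`n x N_T`
#'   true common response), `template` (its species-major
#'   vectorization) and `aberrant` (indices of aberrant trials).
#' @export
gen_template_trials <- function(q = 40, n = 6, N_T = 12, n_aberrant = 8,
                                aberrant_amp = 5, seed = 0L) {
  stopifnot(n_aberrant >= 0, n_aberrant < q)
  with_seed(split_seed(seed, "template_trials"), {
    loading <- runif(n, 0.5, 1.5)
    bump <- exp(-((seq_len(N_T)) - N_T / 2)^2 / (2 * (N_T / 6)^2))
    pattern <- outer(loading, bump)
    template <- as.vector(t(pattern))
    amp <- runif(q, 0.6, 1.4)
    X <- outer(amp, template)
    aberrant <- if (n_aberrant > 0) sample.int(q, n_aberrant) else integer(0)
    for (b in aberrant)
      X[b, ] <- X[b, ] + aberrant_amp * max(abs(template)) * rnorm(n * N_T)
    list(X = data_matrix(X, n, N_T), pattern = pattern,
         template = template, aberrant = sort(aberrant))
  })
}

#' Generate a continuous test stream with embedded response patterns
#'
#' A long `n`-species noise stream with the given pattern added at
#' `n_onsets` known, well-separated positions, scaled so that the
#' pattern-to-noise RMS ratio equals `snr`.  The companion of
#' [gen_template_trials()] for scoring onset detection with
#' [correlation_score()] / [roc_curve()].
#'
#' @param pattern `n x N_T` response pattern (e.g. from
#'   [gen_template_trials()]).
#' @param n_onsets number of embedded events; @param spacing minimum
#'   distance between onset slots in samples; @param snr pattern RMS over
#'   noise RMS.
#' @param seed integer seed.
#' @return list with `stream` (`n x T` matrix) and `onsets` (1-based
#'   start indices).
#' @export
gen_template_stream <- function(pattern, n_onsets = 20, spacing = 60,
                                snr = 2, seed = 0L) {
  n <- nrow(pattern); nt <- ncol(pattern)
  stopifnot(spacing > nt, n_onsets >= 1)
  with_seed(split_seed(seed, "template_stream"), {
    Tlen <- spacing * (n_onsets + 4)
    noise_sd <- sqrt(mean(pattern^2)) / snr
    stream <- matrix(rnorm(n * Tlen, sd = noise_sd), n, Tlen)
    slots <- seq(2 * nt, Tlen - 2 * nt, by = spacing)
    onsets <- sort(sample(slots, n_onsets))
    for (o in onsets)
      stream[, o:(o + nt - 1)] <- stream[, o:(o + nt - 1)] + pattern
    list(stream = stream, onsets = onsets)
  })
}

#' Generate a perturbation panel with latent subtypes in the aberrant part
#'
#' Emulates a drug-perturbation panel whose subtype identity is carried
#' solely by the aberrant component: every trial shares a common
#' low-rank response (rank-2 basis with per-trial mixing weights), while
#' each subtype has a characteristic signature of a few large
#' spikes at subtype-specific (species, time) positions -- concentrated
#' enough that Principal Component Pursuit routes them to the sparse
#' component rather than the low-rank one.  Dense trial noise keeps the
#' signature invisible to raw-correlation clustering.
#'
#' @param q trials (split evenly across subtypes); @param n species;
#'   @param N_T time points.
#' @param n_subtypes number of latent subtypes; default 2.
#' @param n_spikes spikes per subtype signature; default 4.
#' @param spike_amp spike amplitude in panel standard deviations;
#'   default 2.
#' @param noise_sd trial noise in panel standard deviations; default 0.5.
#' @param seed integer seed.
#' @return list with `X` (the [data_matrix()]), `subtype` (true labels),
#'   `common` and `signature` (the generating components).
#' @export
gen_subtype_panel <- function(q = 40, n = 8, N_T = 10, n_subtypes = 2,
                              n_spikes = 4, spike_amp = 2, noise_sd = 0.5,
                              seed = 0L) {
  p <- n * N_T
  stopifnot(q %% n_subtypes == 0, n_subtypes * n_spikes <= p)
  with_seed(split_seed(seed, "subtype_panel"), {
    basis <- matrix(rnorm(2 * p), 2, p)
    coef <- matrix(runif(2 * q, 0.2, 1.8), q, 2)
    common <- coef %*% basis
    sig <- sd(common)
    subtype <- rep(seq_len(n_subtypes), each = q / n_subtypes)
    block <- p %/% n_subtypes
    spots <- lapply(seq_len(n_subtypes),
                    function(k) (k - 1) * block + sample.int(block, n_spikes))
    signs <- lapply(seq_len(n_subtypes),
                    function(k) sample(c(-1, 1), n_spikes, replace = TRUE))
    signature <- matrix(0, q, p)
    for (i in seq_len(q)) {
      k <- subtype[i]
      signature[i, spots[[k]]] <-
        runif(n_spikes, 0.7, 1.3) * spike_amp * sig * signs[[k]]
    }
    X <- common + signature + matrix(rnorm(q * p, sd = noise_sd * sig), q, p)
    list(X = data_matrix(X, n, N_T), subtype = subtype,
         common = common, signature = signature)
  })
}
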
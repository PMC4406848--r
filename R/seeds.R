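#' Derive a named sub-stream seed from a top-level seed
#'
#' Every stochastic stage of the package (projection draw, each generator,
#' each resampling attempt) seeds its own RNG stream derived from the
#' user's single top-level seed and a stage name, so stages are
#' independently reproducible and inserting a new stage does not shift the
#' draws of the others.
#'
#' @param seed integer top-level seed.
#' @param name character stream name, e.g. `"projection"`.
#' @param index optional nonnegative integer for per-attempt sub-streams.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' split_seed(1, "projection")
#' split_seed(1, "projection", index = 3)
#' @export
split_seed <- function(seed, name, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  p <- 2147483629  # largest prime < 2^31 - 18
  h <- 0
  for (ch in utf8ToInt(as.character(name))) h <- (h * 131 + ch) %% p
  x <- (abs(seed) %% p) * 48271 %% p
  out <- (x + h * 69621 + index * 16807) %% (p - 1) + 1
  as.integer(out)
}

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards (functions taking a seed must not disturb the session).
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
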
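# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed
#'
#' One user-facing seed governs several independent random sub-streams
#' (taxonomy, masses, noise, per-trait bootstrap draws). Sub-seeds are derived
#' deterministically from the master seed and a text tag so one stream can be
#' held fixed while another varies. Results stay below 2^31 - 1.
#' @noRd
derive_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 1048573
  as.integer((abs(as.double(seed)) * 7919 + h * 104729 + 1) %% 2147483646L) + 1L
}

# Run expr with a local RNG state when seed is non-NULL; the caller's RNG
# stream is left untouched either way.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Hazen quantile (linear interpolation with h = n*p + 1/2). Fixed here so
# bootstrap percentile intervals are reproducible across platforms.
hazen_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 5, names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
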
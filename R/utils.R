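# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# round-half-away-from-zero (base round() is round-half-even)
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < min) || any(x != floor(x))) {
    stop(sprintf("`%s` must be integer-valued and >= %d", name, min), call. = FALSE)
  }
  invisible(x)
}
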
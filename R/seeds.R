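# Deterministic seed plumbing: one root seed per run, named child seeds per
# stochastic stage, so adding a stage never perturbs earlier stages' draws.

#' Derive a named child seed from a root seed
#'
#' Deterministic hash of `(seed, label)` into a valid 32-bit integer seed.
#' Every stochastic stage of the package draws its own child seed by name,
#' which keeps independent stages independent and whole runs reproducible
#' from a single root seed.
#'
#' @param seed integer root seed.
#' @param label character stage name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * (seq_along(codes) %% 11 + 3))
  as.integer((abs(as.numeric(seed)) * 69621 + h * 7919 + 17) %% 2147483646)
}

# Evaluate `code` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
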
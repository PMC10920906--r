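# internal helpers shared across modules

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
# seed = NULL leaves the RNG alone (draws advance the global stream).
with_seed_local <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a stream-specific child seed so sub-generators don't reuse streams
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    stop("`", name, "` must be a single positive finite number", call. = FALSE)
  }
  invisible(x)
}
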
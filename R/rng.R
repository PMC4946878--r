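# Reproducible substreams: one master seed spawns independent L'Ecuyer-CMRG
# streams (stream k for purpose k), so e.g. adding screens to a simulation
# never perturbs the counts drawn for earlier screens.

rng_stream_state <- function(seed, stream_index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.numeric(stream_index), stream_index >= 0)
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_kind <- RNGkind()
  on.exit({
    suppressWarnings(RNGkind(old_kind[1L], old_kind[2L], old_kind[3L]))
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
  set.seed(as.integer(seed %% .Machine$integer.max))
  state <- get(".Random.seed", envir = globalenv())
  for (i in seq_len(stream_index)) state <- parallel::nextRNGStream(state)
  state
}

# Evaluate `expr` under the given .Random.seed state, restoring the caller's
# RNG state afterwards.
with_rng_state <- function(state, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  assign(".Random.seed", state, envir = globalenv())
  expr
}

# Deterministic vector of per-replicate seeds below 2^31, derived from one
# master seed.
spawn_seeds <- function(seed, n) {
  with_rng_state(rng_stream_state(seed, 0L), sample.int(2147483646L, n))
}
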
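# RNG plumbing. A master seed spawns one L'Ecuyer-CMRG substream per gene plus
# one "meta" stream for gene-level draws (baseline means, DE assignment, fold
# changes). Each gene's counts therefore depend only on (master_seed, gene
# index), never on how many genes happen to be differentially expressed, and
# every consumer of a dataset sees bit-identical counts.

save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

set_stream <- function(stream) {
  assign(".Random.seed", stream, envir = globalenv())
  invisible(NULL)
}

# Derive `n_streams` independent L'Ecuyer-CMRG substreams from a master seed.
# The caller's RNG state is left untouched.
derive_streams <- function(master_seed, n_streams) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, master_seed >= 0)
  old <- save_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(master_seed %% (.Machine$integer.max - 1)),
           kind = "L'Ecuyer-CMRG")
  streams <- vector("list", n_streams)
  s <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  for (i in seq_len(n_streams)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

# Pre-derived per-iteration seeds (all below 2^31) so results are independent
# of execution order.
derive_iteration_seeds <- function(master_seed, n) {
  old <- save_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(master_seed %% (.Machine$integer.max - 1)))
  sample.int(.Machine$integer.max - 1L, n)
}
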
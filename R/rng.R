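# Independent RNG streams.
#
# A run consumes randomness for several unrelated purposes: Q-value
# initialisation, the train/test split, exploration coins, guide coins and
# classifier seeds. Each purpose gets its own stream derived from the master
# seed, so that e.g. disabling the guide agents does not shift the
# exploration coins of the main agents. Streams are implemented by swapping
# .Random.seed states in and out of the global environment.

STREAM_OFFSETS <- c(init = 1L, split = 2L, explore = 3L, guide = 4L,
                    classifier = 5L, ga = 6L, synth = 7L)

derive_seed <- function(master_seed, offset) {
  # stay well inside 32-bit integer range
  as.integer((as.numeric(master_seed) * 7919 + 104729 * offset) %% 2147483647)
}

new_rng_stream <- function(seed) {
  stream <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  stream$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  stream
}

rng_streams <- function(master_seed, which = names(STREAM_OFFSETS)) {
  streams <- lapply(which, function(nm) {
    new_rng_stream(derive_seed(master_seed, STREAM_OFFSETS[[nm]]))
  })
  names(streams) <- which
  streams
}

# Evaluate `expr` with the stream's RNG state active; the stream advances,
# the caller's global RNG state is untouched.
with_stream <- function(stream, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# A fresh integer seed drawn from a stream (for seeding the C++ classifier).
stream_int <- function(stream) {
  with_stream(stream, sample.int(2147483646L, 1L))
}

# Order-sensitive integer hash of a 0/1 mask (binary fold mod a prime).
mask_hash <- function(mask) {
  h <- 0
  for (b in mask) h <- (h * 2 + b) %% 2147483629
  as.integer(h)
}
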
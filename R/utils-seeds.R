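# Counter-based substream seeds: one user-facing integer seed expands into
# per-operation streams so pipeline stages can be reordered without
# perturbing each other's draws.

#' Derive a substream seed from a global seed and a counter
#'
#' Mixes a global integer seed with an operation counter through two rounds
#' of integer hashing (exact in double precision) and reduces modulo
#' 2^31 - 1, so every stage of a pipeline gets its own reproducible stream.
#'
#' @param seed Global integer seed.
#' @param counter Non-negative integer identifying the operation (or
#'   replicate) within the run.
#' @return A single integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @examples
#' substream_seed(42, 0)
#' substream_seed(42, 1)
#' @export
substream_seed <- function(seed, counter = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed),
            is.numeric(counter), length(counter) == 1, counter >= 0)
  m <- 2147483647 # 2^31 - 1 (prime)
  h <- abs(as.double(seed)) %% m
  h <- (h * 69069 + 1234567) %% m
  h <- (h + (as.double(counter) %% m) * 104729) %% m
  h <- (h * 48271 + 11) %% m
  h <- (h * 69069 + 1) %% m
  as.integer(h %% (m - 2)) + 1L
}

# set.seed() from a substream unless seed is NULL (leave RNG state alone)
.seed_substream <- function(seed, counter) {
  if (!is.null(seed)) set.seed(substream_seed(seed, counter))
  invisible(NULL)
}
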
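#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from a single master seed. Per-patient
#' and per-permutation seeds are derived by fixed integer arithmetic on
#' (master seed, stream id, index), so serial and parallel execution — and any
#' execution order — produce identical results.
#'
#' The mixing function is three rounds of the Lehmer/Park–Miller step
#' x -> (48271 * x) mod (2^31 - 1), interleaved with the stream and index
#' offsets. All intermediates stay below 2^53, so the arithmetic is exact in
#' doubles; the result is a strictly positive integer below 2^31 - 1.
#'
#' @param master_seed integer master seed.
#' @param stream integer stream identifier (e.g. 1 = patients,
#'   2 = permutations, 3 = relabelings).
#' @param index non-negative integer index within the stream.
#' @return an integer seed suitable for [set.seed()].
#' @export
derive_seed <- function(master_seed, stream = 1L, index = 0L) {
  m <- 2147483647
  step <- function(x) (48271 * (x %% m)) %% m
  x <- step((abs(as.numeric(master_seed)) %% m) + 1)
  x <- step((x + as.numeric(stream) * 1000003) %% m)
  x <- step((x + as.numeric(index) * 9973) %% m)
  as.integer(x %% (m - 1) + 1)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
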
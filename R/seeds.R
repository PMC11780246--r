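#' Derive a reproducible sub-seed
#'
#' Deterministically mixes a master seed with a stream label and an index into
#' a new seed in `[1, 2^31 - 2]`. Each (stream, index) pair gets its own seed,
#' so per-subject draws are independent sub-streams of the master seed:
#' enlarging a cohort, reordering scenarios, or re-drawing one subject never
#' reshuffles the draws of any other subject.
#'
#' The mixing is three rounds of a Lehmer step (multiplier 48271 modulo the
#' Mersenne prime 2^31 - 1), folding in `stream` and `index` between rounds.
#' All arithmetic stays below 2^53 so it is exact in doubles.
#'
#' @param seed master seed, a single integer.
#' @param stream integer stream label (e.g. one constant per sampling stage).
#' @param index non-negative integer index within the stream (e.g. subject
#'   number or replicate number).
#' @return A single integer seed suitable for [set.seed()].
#' @examples
#' derive_seed(42, 1, 7)
#' @export
derive_seed <- function(seed, stream = 0L, index = 0L) {
  m <- 2147483647 # 2^31 - 1
  a <- 48271
  lehmer <- function(x) (a * (x %% m)) %% m
  x <- lehmer((abs(as.numeric(seed)) %% m) + 1)
  x <- lehmer((x + as.numeric(stream)) %% m)
  x <- lehmer((x + as.numeric(index)) %% m)
  as.integer(x %% (m - 1) + 1)
}

# stream labels for the sampling stages (internal)
.STREAM_PK <- 101L
.STREAM_AE <- 202L
.STREAM_CHAIN <- 303L
.STREAM_REPLICATE <- 404L

#' Evaluate an expression under a local RNG state
#'
#' Saves and restores `.Random.seed` so library code does not disturb the
#' caller's RNG stream.
#' @param seed seed for the local state.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
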
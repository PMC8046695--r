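#' Seeded uniform random streams
#'
#' The simulator draws all of its noise from counter-style splitmix64 streams
#' so that every run is reproducible from `(seed, stream id)` alone and
#' replicate subnetworks are statistically independent.  Stream ids used by
#' the engine are `stage_index * 256 + input_index` (both 0-based).
#'
#' @param seed Integer base seed (kept below 2^31).
#' @param stream Integer stream id.
#' @param n Number of uniforms to draw.
#' @return Numeric vector of `n` i.i.d. Uniform(0, 1) draws.
#' @export
unif_stream <- function(seed, stream, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), length(stream) == 1L, stream >= 0,
            n >= 0)
  cpp_unif_stream(as.double(seed), as.double(stream), as.integer(n))
}

#' Derive distinct replicate seeds from one base seed
#'
#' @param seed Integer base seed.
#' @param n Number of replicate seeds required.
#' @return Integer vector of `n` distinct seeds in `[1, 2^31 - 1]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(n >= 1)
  u <- unif_stream(seed, stream = 97L, n = 4L * n + 16L)
  s <- unique(as.integer(floor(u * (2^31 - 2))) + 1L)
  if (length(s) < n) stop("could not derive ", n, " distinct seeds")
  s[seq_len(n)]
}
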
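#' Derive a child seed for a named random stream
#'
#' A single experiment seed is expanded into per-stream child seeds so any
#' one data stream (crop yields, one plot's fluxes, an OTU table, ...) can
#' be regenerated on its own without replaying the whole dataset. The
#' scheme is fixed and documented: a base-31 polynomial hash of the stream
#' label is folded into the parent seed modulo 2147483647 (2^31 - 1), so
#' child seeds always fit a 32-bit integer.
#'
#' @param seed integer parent seed.
#' @param stream character label of the stream, e.g. `"flux/P04/n2o"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @examples
#' child_seed(1, "flux/P01/n2o")
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed),
            is.character(stream))
  h <- 0
  for (k in utf8ToInt(paste(stream, collapse = "/"))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Evaluate `code` under the RNG state implied by child_seed(seed, stream),
# restoring the caller's RNG state afterwards.
with_stream_seed <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed(child_seed(seed, stream))
  force(code)
}
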
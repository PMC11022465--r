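#' Derive a child seed for a named random stream
#'
#' One top-level seed fans out to independent per-stream seeds by stable
#' hashing of the stream name, so adding a new stream never perturbs the
#' draws of existing ones. The hash is a 31-bit multiplicative string hash
#' combined with the parent seed; all arithmetic stays exact in doubles.
#'
#' @param seed integer parent seed.
#' @param stream character scalar naming the stream (e.g. "left_foot").
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, "left_foot") != child_seed(1, "right_foot")
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream),
            length(stream) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (code in utf8ToInt(stream)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
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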
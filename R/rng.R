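#' Derive a child seed from a master seed and a stream label
#'
#' All stochastic stages draw their seeds through this helper so that a single
#' master seed reproduces an entire multi-stage pipeline while stages remain
#' independently re-runnable. The derived seed is kept strictly below 2^31.
#'
#' @param master integer master seed.
#' @param stream character label naming the consumer (e.g. `"genotypes"`).
#' @return A single integer seed.
#' @export
child_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(master) * 69069 + h * 2654435761) %% 2147483647L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
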
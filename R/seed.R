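#' Derive an independent child seed from a master seed
#'
#' All stochastic stages of the pipeline draw their randomness from child
#' seeds split off a single master seed, so that (a) a whole analysis is
#' reproducible from one integer and (b) different generators or iterations
#' never share an RNG stream. The splitting rule is the affine map
#' \deqn{child = (seed \cdot 48271 + stream \cdot 104729) \bmod (2^{31}-1)}
#' mapped into `1..2^31-2` (48271 is the MINSTD multiplier, 104729 the
#' 10000th prime). It is deterministic, cheap, and keeps all seeds within
#' the 32-bit integer range R requires.
#'
#' @param seed Master seed, a non-negative integer below 2^31.
#' @param stream Stream index (non-negative integer); distinct streams give
#'   distinct child seeds for any fixed master seed.
#' @return A positive integer seed suitable for [set.seed()].
#' @examples
#' child_seed(1, 1)
#' child_seed(1, 2)
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0,
            is.numeric(stream), length(stream) == 1, stream >= 0)
  m <- 2147483647 # 2^31 - 1
  s <- as.double(seed) %% m
  child <- (s * 48271 + as.double(stream) %% m * 104729) %% m
  as.integer(child %% (m - 1) + 1)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
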
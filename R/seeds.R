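#' Derive child seeds from a root seed
#'
#' Experiments take one root seed and split it deterministically into one
#' seed per stochastic stage, so that a whole pipeline is reproducible from
#' a single integer while stages stay statistically independent.
#'
#' @param seed Integer root seed.
#' @param n Number of child seeds to derive.
#' @return Integer vector of length `n`, each in `[1, .Machine$integer.max)`.
#' @export
#' @examples
#' derive_seeds(1L, 3L)
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(n), n >= 1L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, as.integer(n))
}

get_rng_state <- function() {
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

# Run `expr` under `seed` if non-NULL, leaving the caller's RNG stream
# untouched; with seed = NULL the global stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}
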
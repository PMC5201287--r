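## Named random-number substreams.
##
## One root seed spawns independent, named substreams (cohort, incidence,
## choice, outcome, vitals, parameters ...) so that a policy lever perturbs
## only the draws it actually touches.  Streams are stored as saved
## .Random.seed states and swapped in and out around each block of draws;
## this is what makes common-random-number pairing across scenario arms work.

#' Derive a deterministic child seed from a root seed and a stream name
#'
#' @param base_seed non-negative integer root seed
#' @param name character stream label
#' @return an integer seed in [0, 2^31)
#' @keywords internal
substream_seed <- function(base_seed, name) {
  stopifnot(is.numeric(base_seed), length(base_seed) == 1L, base_seed >= 0)
  ## rolling polynomial hash over the label bytes, folded with the root
  ## seed; all arithmetic stays below 2^53 so doubles are exact
  m <- 2147483647  # 2^31 - 1
  h <- 17
  for (b in utf8ToInt(name)) h <- (h * 131 + b) %% m
  h <- (h * 48271 + (base_seed %% m) * 16807) %% m
  as.integer(h)
}

#' Create a set of named RNG streams
#'
#' @param base_seed integer root seed
#' @param names character vector of stream labels
#' @return an environment mapping label -> saved RNG state
#' @keywords internal
rng_streams <- function(base_seed, names) {
  streams <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  for (nm in names) {
    set.seed(substream_seed(base_seed, nm))
    assign(nm, get(".Random.seed", globalenv()), envir = streams)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  streams
}

#' Evaluate an expression under a named stream, saving the state back
#' @keywords internal
with_stream <- function(streams, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  on.exit({
    assign(name, get(".Random.seed", globalenv()), envir = streams)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
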
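#' @useDynLib chirpcode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom mclust Mclust mclustBIC
NULL

# Evaluate `code` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Population variance (n denominator), the convention used by the quality
# index so numerator and denominator are on the same scale.
pop_var <- function(x) mean((x - mean(x))^2)

# spikes of all trials of a unit as one vector
all_spikes <- function(trials) unlist(trials, use.names = FALSE)
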
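# Seed plumbing: one master seed per top-level call, child seeds derived by
# fixed offsets so that independent stages draw from independent streams.

#' Derive a child seed from a master seed
#'
#' Deterministic map from `(seed, offset)` to a new seed below 2^31, used to
#' give each internal stage (site generation, absence subsampling, bootstrap
#' replicates, MCMC chains...) its own reproducible stream.
#'
#' @param seed Integer master seed.
#' @param offset Integer offset identifying the stage.
#' @return An integer seed.
#' @export
child_seed <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) * 977 + 101 * as.numeric(offset) + 13) %%
               2147483629)
}

# Evaluate `code` under `seed` without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
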
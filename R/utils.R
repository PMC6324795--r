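# Deterministic seed streams -------------------------------------------------
#
# Every stochastic ingredient of a scenario (synapse placement, presynaptic
# spike times, somatic noise) draws from its own named stream so that one can
# be re-randomized while the others are held fixed (noise-off controls, common
# input comparisons, representative re-seeding). Streams are derived from a
# base seed by 32-bit-safe modular folding; all values stay below 2^31.

.SEED_MOD <- 2147483563

#' Derive a deterministic sub-seed from a base seed
#'
#' Folds a base seed and any number of integer-coercible components into a
#' new seed in `[1, 2^31 - 2]`. Used throughout the package to give each
#' random stream (synapse placement, spike times, per-group trains, somatic
#' noise, re-seeded replicates) its own reproducible seed.
#'
#' @param seed Base integer seed.
#' @param ... Integer components (stream ids, grid coordinates, replicate
#'   indices). Character values are hashed by character code.
#' @return A single integer seed.
#' @examples
#' derive_seed(1, "spikes", 3)
#' @export
derive_seed <- function(seed, ...) {
  h <- as.double(seed) %% .SEED_MOD
  for (x in list(...)) {
    if (is.character(x)) x <- utf8ToInt(paste(x, collapse = ""))
    for (xi in as.double(x)) {
      xi <- xi %% .SEED_MOD
      h <- (h * 69069 + xi + 1) %% .SEED_MOD
    }
  }
  as.integer(h + 1)
}

#' Seeds for the independent random streams of one scenario
#'
#' @param seed Scenario base seed.
#' @param replicate Replicate index (re-seeded representative checks).
#' @return Named list with `placement`, `spikes`, `grouping` and `noise`
#'   seeds.
#' @export
scenario_seeds <- function(seed, replicate = 1L) {
  list(
    placement = derive_seed(seed, "placement", replicate),
    spikes    = derive_seed(seed, "spikes", replicate),
    grouping  = derive_seed(seed, "grouping", replicate),
    noise     = derive_seed(seed, "noise", replicate)
  )
}

# run code under a temporary RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
}
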
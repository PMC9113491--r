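# Deterministic derivation of per-branch RNG substreams, so that the result
# of a simulation depends only on (seed, replicate, node id) and never on
# traversal order. Arithmetic stays below 2^53 so doubles are exact.

SEED_MOD <- 2147483647 # 2^31 - 1

derive_seed <- function(seed, rep, node) {
  x <- as.numeric(seed) %% SEED_MOD
  for (v in c(rep, node, 1)) {
    x <- (x * 69069 + as.numeric(v) + 1) %% SEED_MOD
    x <- (x * 6364136 + 1442695) %% SEED_MOD
  }
  as.integer(x)
}

with_branch_seed <- function(seed, rep, node, expr) {
  set.seed(derive_seed(seed, rep, node))
  expr
}
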
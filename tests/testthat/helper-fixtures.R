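# Shared fixtures: all built in code, nothing read from disk.

# The classical 1000-dimensional worked configuration: one million hard
# locations, radius 451, 10,000 stored items, target written once, with
# the nominal assembly size of 1000 locations per operation.
canonical_params <- function(w = 1, s = 1e4, h = 1000) {
  theory_params(n = 1000, H = 1e6, r = 451, s = s, w = w, h = h)
}

# A small memory that activates a healthy assembly (~5% fraction), used
# where empty activation sets would otherwise be a nuisance at tiny n.
tiny_store <- function(n = 64, H = 400, fraction = 0.05, seed = 1) {
  sdm(sdm_config(n, H, fraction = fraction, seed = seed))
}

# Deterministic m x n matrix of random items.
random_items <- function(m, n, seed) {
  withr::with_seed(seed,
    matrix(as.double(stats::rbinom(m * n, 1, 0.5)), nrow = m, ncol = n))
}
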
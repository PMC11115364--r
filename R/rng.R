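# Seed plumbing: every stochastic operation takes an explicit seed and
# derives per-stage sub-seeds deterministically, so pipelines replay exactly.

local_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Deterministic 32-bit sub-seed: distinct k give distinct streams for the
# same master seed. Kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 97651L * 65537 + as.double(k) * 10007 + 1) %%
               2147483629)
}
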
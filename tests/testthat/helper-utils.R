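rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# independent hand constants for oracle arithmetic in tests
HC <- 6.62607015e-34 * 2.99792458e8   # J m
NA_CONST <- 6.02214076e23

# random strictly positive rate sets on log-uniform scales, seeded
random_rate_sets <- function(n, seed = 1, lo = 1e2, hi = 1e8) {
  set.seed(seed)
  replicate(n, {
    v <- exp(stats::runif(4, log(lo), log(hi)))
    rate_set(v[1], v[2], v[3], v[4])
  }, simplify = FALSE)
}
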
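# Independent oracles used by the test suite. These deliberately avoid the
# package's own enumeration/entropy code paths.

# Compare against a printed (rounded) value at an ABSOLUTE tolerance;
# expect_equal's tolerance is relative, which is the wrong yardstick for
# values the source rounds to a fixed number of decimals.
expect_printed <- function(actual, printed, tol) {
  testthat::expect_lt(abs(actual - printed), tol)
}

# Brute-force joint entropy: recursively enumerate every complete value
# assignment over a list of per-chain distributions (independence) and sum
# -p log p directly.
brute_entropy <- function(dists, base = 10) {
  probs <- 1
  for (p in dists) probs <- as.vector(outer(probs, p))
  probs <- probs[probs > 0]
  -sum(probs * log(probs, base = base))
}

# Total-variation distance between two named distributions on a shared
# value space.
tv_dist <- function(p, q) {
  q <- q[names(p)]
  sum(abs(p - q)) / 2
}

# The printed holiday-resort t1 distributions.
resort_dists <- list(habitat = c(tropics = 0.9, moderate = 0.1),
                     height = c(tall = 0.6, small = 0.4))

resort_t1_frame <- function() stochastic_frame("plant", dist = resort_dists)
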
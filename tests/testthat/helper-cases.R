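# Shared case generators for property-style tests.

# All 11 figure fixtures bound at their registry defaults.
allFixturesBound <- function() {
  lapply(setNames(nm = fixtureNames()), function(nm) bindFixture(nm))
}

# A deterministic spread of random resident parameter sets covering both
# regimes and every admissible leading compartment. Returns a list of lists
# with elements params, regime, j0.
randomCases <- function(nSets, n = 4L, seedOffset = 0L) {
  regimes <- c("expanding", "homeostatic")
  out <- vector("list", nSets)
  for (s in seq_len(nSets)) {
    regime <- regimes[(s %% 2) + 1]
    j0 <- ((s %/% 2) %% (n - 1)) + 1
    out[[s]] <- list(
      params = randomParams(seedOffset + s, regime, j0Target = j0, n = n),
      regime = regime, j0 = j0)
  }
  out
}

expect_delta_equal <- function(a, b, tol) {
  expect_lt(abs(a - b), tol)
}
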
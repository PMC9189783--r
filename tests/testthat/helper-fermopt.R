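# shared fixtures and small oracles for the test suite

toy_factors <- function(k = 2L) {
  factor_set(paste0("f", seq_len(k)), low = rep(0, k), high = rep(2, k))
}

study_runs <- function() fermopt_fixture("ccrd_runs")

study_design <- function() {
  design_from_actual(study_runs()[, c("cpe", "csl", "casein", "mg", "mn")],
                     protease_factors())
}

# relative agreement helper for values reproduced from print-rounded inputs
expect_rel <- function(actual, expected, rel) {
  expect_lt(abs(actual - expected) / abs(expected), rel)
}
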
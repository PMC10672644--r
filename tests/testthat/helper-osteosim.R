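# Shared fixtures: a small two-site ensemble and short spans keep the
# engine-level tests fast; full-scale runs live in test-acceptance.R.

tiny_ensemble <- function() {
  bone_ensemble(v_b = c(0.85, 0.35), weight = c(0.6, 0.4))
}

# independent quintic evaluation for the specific-surface oracle
sv_oracle <- function(p, coef = c(32.3, -93.9, 134, -101, 28.8)) {
  sum(coef * p^seq_along(coef))
}

expect_rel_equal <- function(actual, expected, tol = 1e-10) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
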
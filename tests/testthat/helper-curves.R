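# Shared test helpers: small deterministic curves and registry builders.

# A smooth positive conditional hazard on the default grid.
test_conditional_curve <- function(g = age_grid()) {
  hazard_curve(1e-4 * exp(0.08 * (g$midpoints - 20)), age_grid = g,
               kind = "conditional")
}

# Noiseless registry: expected counts used as (real-valued) cases.
noiseless_table <- function(params) {
  registry_table(expected_counts(params), params$population_template,
                 age_grid = params$age_grid, period_grid = params$period_grid,
                 label = "noiseless", real_cases = TRUE)
}

# Default analysis config matching the fixture layout.
default_config <- function(...) {
  run_config(title = "test", ...)
}

# Generating parameters with nonzero period and cohort effects that satisfy
# the fitter's identifiability conventions (anchored zeros, zero cohort trend).
recovery_params <- function(seed = 1L) {
  J <- 7L; n <- 16L; K <- n + J - 1L
  b <- 0.04 * (seq_len(J) - 4L)        # zero at the anchored period 4
  k_star <- 4L - 11L + n               # = 9
  c_raw <- 0.15 * sin(seq_len(K) / 3)
  cc <- constrain_cohort_effects(c_raw, k_star)
  sim_params(p_true = 0.012, period_effects_true = b,
             cohort_effects_true = cc, seed = seed)
}
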
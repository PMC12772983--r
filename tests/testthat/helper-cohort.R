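# The default synthetic cohort takes a few minutes to simulate and
# feature-extract, so it is built lazily once per test run and shared.
.cohort_cache <- new.env(parent = emptyenv())

default_cohort_run <- function() {
  if (!is.null(.cohort_cache$run)) return(.cohort_cache$run)
  sim <- simulate_cohort(cohort_sim_config(seed = 42))
  cohort <- extract_cohort_features(sim$recordings)
  analysis <- run_full_analysis(cohort, seed = 42)
  .cohort_cache$run <- list(sim = sim, cohort = cohort, analysis = analysis)
  .cohort_cache$run
}
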
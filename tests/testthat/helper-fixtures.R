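# shared fixtures, cached so the baseline cohort runs happen once per suite

.cache <- new.env(parent = emptyenv())

get_fixture <- function(tech = "SOC") {
  key <- paste0("spec_", tech)
  if (is.null(.cache[[key]])) .cache[[key]] <- wbrt_fixture(tech)
  .cache[[key]]
}

get_result <- function(tech = "SOC") {
  key <- paste0("res_", tech)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- run_cohort(get_fixture(tech))$result
  .cache[[key]]
}

all_results <- function() {
  lapply(stats::setNames(nm = wbrt_techniques()), get_result)
}

# minimal one-live-state model: cohort stays in NED, utility schedule u
single_state_spec <- function(u = 0.8, horizon = 15L, rate = 0.03,
                              timing = "end", half_cycle = FALSE) {
  model_spec(
    config = model_config(horizon_cycles = horizon, discount_rate = rate,
                          reward_timing = timing,
                          half_cycle_correction = half_cycle,
                          reference_strategy = "ONLY"),
    states = list(health_state("NED", utility = piecewise(0, horizon, u),
                               is_initial = TRUE)),
    transitions = list(),
    technique = technique_profile("ONLY", upfront_cost = 1))
}

expect_spec_equal <- function(a, b, tolerance = 1e-9) {
  expect_equal(wbrtcea:::spec_to_list(a), wbrtcea:::spec_to_list(b),
               tolerance = tolerance)
}
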
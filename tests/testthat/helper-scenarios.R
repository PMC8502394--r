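# Small scenarios built in code for unit tests.

# Fully deterministic feeder: `arrivals` completed referrals per period, all
# with-condition, and a workforce giving a fixed new-start capacity of
# `providers * slots` (treatment duration 1, so slots clear every period).
deterministic_scenario <- function(arrivals = 10, providers = 2, slots = 4,
                                   n_periods = 12, n_runs = 2, seed = 7,
                                   queue = list(), workforce = list(),
                                   feedback = list()) {
  scenario_config(
    name = "unit_deterministic",
    population = list(cohort_inflow_per_period = arrivals, prevalence = 1,
                      reach = 1, n_periods = n_periods),
    instrument = list(mean_score_negative = 0, mean_score_positive = 2,
                      sd_score_negative = 1, sd_score_positive = 1,
                      threshold = -30),
    cascade = list(p_referral_given_positive_with_condition = 1,
                   p_referral_given_positive_without_condition = 1,
                   p_completion_with_condition = 1,
                   p_completion_without_condition = 1),
    workforce = utils::modifyList(list(initial_providers = providers,
                                       slots_per_provider_per_period = slots,
                                       treatment_duration_periods = 1),
                                  workforce),
    queue = queue,
    feedback = feedback,
    run = list(n_runs = n_runs, base_seed = seed)
  )
}

# Small stochastic scenario with ample capacity, for metric checks.
ample_capacity_scenario <- function(n_periods = 10, n_runs = 4, seed = 11,
                                    threshold = 1, reach = 0.9) {
  scenario_config(
    name = "unit_ample",
    population = list(cohort_inflow_per_period = 200, prevalence = 0.5,
                      reach = reach, n_periods = n_periods),
    instrument = list(mean_score_negative = 0, mean_score_positive = 2,
                      sd_score_negative = 1, sd_score_positive = 1,
                      threshold = threshold),
    cascade = list(p_referral_given_positive_with_condition = 0.8,
                   p_referral_given_positive_without_condition = 0.6,
                   p_completion_with_condition = 0.9,
                   p_completion_without_condition = 0.7),
    workforce = list(initial_providers = 50,
                     slots_per_provider_per_period = 10,
                     treatment_duration_periods = 1),
    run = list(n_runs = n_runs, base_seed = seed)
  )
}

# A minimal valid scenario document as a nested list (for YAML tests).
minimal_scenario_doc <- function() {
  list(
    schema = 1L,
    name = "minimal",
    population = list(cohort_inflow_per_period = 50, prevalence = 0.3,
                      reach = 0.8, n_periods = 6),
    instrument = list(mean_score_negative = 0, mean_score_positive = 1,
                      sd_score_negative = 1, sd_score_positive = 1,
                      threshold = 0.5),
    cascade = list(p_referral_given_positive_with_condition = 0.7,
                   p_referral_given_positive_without_condition = 0.5,
                   p_completion_with_condition = 0.6,
                   p_completion_without_condition = 0.4),
    workforce = list(initial_providers = 3,
                     slots_per_provider_per_period = 8,
                     treatment_duration_periods = 2)
  )
}
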
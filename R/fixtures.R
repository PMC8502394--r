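#' Specification for a randomized test scenario
#'
#' Fixture regimes make each qualitative system behaviour reproducibly
#' testable: waitlist growth needs demand above capacity, the threshold
#' trade-off needs a binding capacity constraint, and fluid-limit oracles
#' need a fully deterministic system.
#'
#' Regimes:
#' * `over_capacity` — expected completed referrals per period exceed the
#'   initial steady-state treatment throughput (waitlists must grow);
#' * `under_capacity` — throughput at least twice expected demand;
#' * `balanced` — throughput within about 25% of expected demand;
#' * `feedback_on` — over-capacity with waitlist feedback loops enabled;
#' * `deterministic` — every probability is 0 or 1 and quits/dropout/misses
#'   are off, so trajectories are exactly the fluid limit.
#'
#' @param regime One of the regime labels above.
#' @param seed Integer seed making [sample_scenario()] deterministic.
#' @param n_periods Simulation horizon for sampled scenarios.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(regime = c("over_capacity", "under_capacity",
                                    "balanced", "feedback_on",
                                    "deterministic"),
                         seed = 1, n_periods = 36) {
  structure(list(regime = match.arg(regime), seed = seed,
                 n_periods = n_periods), class = "fixture_spec")
}

#' Sample a random scenario satisfying a fixture regime
#'
#' Parameters are drawn uniformly within plausible bounds, then the initial
#' provider count is solved from the expected completed-referral rate (via
#' [expected_cascade()]) so the regime's demand/capacity relation holds by
#' construction; the relation is re-verified before returning. Identical
#' spec and seed give identical scenarios.
#'
#' @param spec A [fixture_spec()].
#' @return A validated `scenario_config`.
#' @export
sample_scenario <- function(spec) {
  set.seed(spec$seed)
  runif1 <- function(lo, hi) stats::runif(1, lo, hi)

  if (spec$regime == "deterministic") {
    cfg <- scenario_config(
      name = sprintf("fixture_deterministic_%d", spec$seed),
      population = list(
        cohort_inflow_per_period = sample(5:40, 1),
        prevalence = sample(0:1, 1), reach = 1,
        n_periods = spec$n_periods),
      instrument = list(mean_score_negative = 0, mean_score_positive = 2,
                        sd_score_negative = 1, sd_score_positive = 1,
                        threshold = -30),  # Se = 1 to double precision
      cascade = list(p_referral_given_positive_with_condition = 1,
                     p_referral_given_positive_without_condition = 1,
                     p_completion_with_condition = 1,
                     p_completion_without_condition = 1),
      workforce = list(initial_providers = sample(1:6, 1),
                       slots_per_provider_per_period = sample(2:6, 1),
                       treatment_duration_periods = 1),
      run = list(n_runs = 2, base_seed = spec$seed)
    )
    return(cfg)
  }

  duration <- sample(1:4, 1)
  slots <- sample(6:15, 1)
  providers <- sample(2:8, 1)
  cfg <- scenario_config(
    name = sprintf("fixture_%s_%d", spec$regime, spec$seed),
    population = list(
      cohort_inflow_per_period = 100,  # placeholder, solved below
      prevalence = runif1(0.15, 0.6),
      reach = runif1(0.5, 1),
      n_periods = spec$n_periods),
    instrument = list(
      mean_score_negative = 0,
      mean_score_positive = runif1(0.8, 2.5),
      sd_score_negative = runif1(0.7, 1.3),
      sd_score_positive = runif1(0.7, 1.3),
      threshold = runif1(0, 1.5)),
    cascade = list(
      p_referral_given_positive_with_condition = runif1(0.5, 0.95),
      p_referral_given_positive_without_condition = runif1(0.3, 0.9),
      p_completion_with_condition = runif1(0.4, 0.9),
      p_completion_without_condition = runif1(0.3, 0.8)),
    workforce = list(
      initial_providers = providers,
      slots_per_provider_per_period = slots,
      treatment_duration_periods = duration,
      quit_prob_per_period = runif1(0, 0.02),
      hiring_rule = "none"),
    queue = list(
      waitlist_dropout_prob_per_period = runif1(0, 0.03),
      missed_appointment_prob = runif1(0, 0.1),
      missed_slot_wasted = TRUE),
    run = list(n_runs = 4, base_seed = spec$seed)
  )

  # per-entrant completed-referral probability; demand scales linearly in
  # inflow, so solve inflow against the sampled steady-state throughput
  # (slots/duration starts per provider per period)
  ec <- expected_cascade(cfg)
  p_complete <- sum(ec$expected[ec$stage == "completed_referral"]) /
    cfg$population$cohort_inflow_per_period
  throughput <- providers * slots / duration
  inflow <- switch(spec$regime,
    over_capacity = , feedback_on = ceiling(2 * throughput / p_complete),
    under_capacity = max(1, floor(0.5 * throughput / p_complete)),
    balanced = max(1, round(throughput / p_complete))
  )
  cfg$population$cohort_inflow_per_period <- inflow
  demand <- inflow * p_complete

  ok <- switch(spec$regime,
    over_capacity = , feedback_on = demand > throughput,
    under_capacity = throughput >= 2 * demand,
    balanced = abs(throughput - demand) / throughput <= 0.25
  )
  if (!isTRUE(ok)) {
    stop(sprintf("infeasible fixture bounds for regime '%s' (seed %d)",
                 spec$regime, spec$seed), call. = FALSE)
  }

  if (spec$regime == "feedback_on") {
    cfg$feedback <- list(enabled = TRUE,
                         wait_scale_periods = runif1(3, 12),
                         max_referral_suppression = runif1(0.1, 0.6),
                         max_completion_suppression = runif1(0.1, 0.6),
                         max_quit_amplification = runif1(0.2, 2))
    cfg$workforce$quit_prob_per_period <- runif1(0.005, 0.03)
  }
  validate_scenario(cfg)
}

#' Write the bundled fixture scenarios to disk
#'
#' Writes `baseline.yaml`, `raised_threshold.yaml` and one sampled scenario
#' per fixture regime (fixed seeds) into `dir`.
#'
#' @param dir Output directory, created if needed.
#' @return Character vector of the written paths, invisibly.
#' @export
write_fixture_scenarios <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    baseline = file.path(dir, "baseline.yaml"),
    raised_threshold = file.path(dir, "raised_threshold.yaml")
  )
  save_scenario(make_baseline_scenario(), paths[["baseline"]])
  save_scenario(make_raised_threshold_scenario(), paths[["raised_threshold"]])
  for (regime in c("over_capacity", "under_capacity", "balanced",
                   "feedback_on", "deterministic")) {
    p <- file.path(dir, paste0(regime, ".yaml"))
    save_scenario(sample_scenario(fixture_spec(regime, seed = 101)), p)
    paths[[regime]] <- p
  }
  invisible(paths)
}
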
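#' Build a scenario configuration
#'
#' A scenario is the complete parameterization of one simulated screening
#' system: the entering population, the screening instrument, the referral
#' cascade, the treatment workforce, the queue, optional waitlist feedback
#' loops, and run control. Omitted optional blocks receive documented
#' defaults (feedback disabled, no waitlist dropout, no missed appointments,
#' 20-run ensembles).
#'
#' @param name Non-empty scenario label.
#' @param population List with `cohort_inflow_per_period` (entrants per
#'   period, non-negative integer), `prevalence` (probability an entrant
#'   truly has the condition), `reach` (probability an entrant is screened),
#'   `n_periods` (simulation horizon), and optionally `periods_per_year`
#'   (default 12; periods are months unless overridden).
#' @param instrument List with latent-score means and standard deviations for
#'   the condition-negative and condition-positive classes
#'   (`mean_score_negative`, `mean_score_positive`, `sd_score_negative`,
#'   `sd_score_positive`) and the `threshold` cut-score above which a screen
#'   is positive.
#' @param cascade List with referral-offer and referral-completion
#'   probabilities stratified by true status:
#'   `p_referral_given_positive_with_condition`,
#'   `p_referral_given_positive_without_condition`,
#'   `p_completion_with_condition`, `p_completion_without_condition`.
#' @param workforce List with `initial_providers`,
#'   `slots_per_provider_per_period` (concurrent caseload per provider),
#'   `treatment_duration_periods`, and optionally `quit_prob_per_period`
#'   (default 0), `hiring_rule` (`"none"`, `"reactive"` or `"scheduled"`,
#'   default `"none"`), `hiring_trigger_waitlist_per_provider` (default 3),
#'   `hires_per_trigger` (default 1), `hiring_lag_periods` (default 0) and
#'   `scheduled_hires` (data frame with columns `period`, `count`).
#' @param queue Optional list with `waitlist_dropout_prob_per_period`
#'   (default 0), `missed_appointment_prob` (default 0) and
#'   `missed_slot_wasted` (default `TRUE`: a miss consumes the provider slot
#'   for the period and the person returns to the waitlist head).
#' @param feedback Optional list with `enabled` (default `FALSE`),
#'   `wait_scale_periods` (expected wait at which feedback reaches
#'   half-effect, default 6), `max_referral_suppression`,
#'   `max_completion_suppression` (defaults 0) and `max_quit_amplification`
#'   (default 0).
#' @param run Optional list with `n_runs` (ensemble size, default 20) and
#'   `base_seed` (default 1); run `i` uses seed `base_seed + i - 1`.
#'
#' @return A validated object of class `scenario_config`.
#' @seealso [load_scenario()], [save_scenario()], [make_baseline_scenario()]
#' @export
scenario_config <- function(name, population, instrument, cascade, workforce,
                            queue = list(), feedback = list(), run = list()) {
  cfg <- structure(list(
    schema = 1L,
    name = name,
    population = apply_defaults(population, list(periods_per_year = 12)),
    instrument = as.list(instrument),
    cascade = as.list(cascade),
    workforce = apply_defaults(workforce, list(
      quit_prob_per_period = 0,
      hiring_rule = "none",
      hiring_trigger_waitlist_per_provider = 3,
      hires_per_trigger = 1,
      hiring_lag_periods = 0,
      scheduled_hires = data.frame(period = integer(), count = integer())
    )),
    queue = apply_defaults(queue, list(
      queue_discipline = "fifo",
      waitlist_dropout_prob_per_period = 0,
      missed_appointment_prob = 0,
      missed_slot_wasted = TRUE
    )),
    feedback = apply_defaults(feedback, list(
      enabled = FALSE,
      wait_scale_periods = 6,
      max_referral_suppression = 0,
      max_completion_suppression = 0,
      max_quit_amplification = 0
    )),
    run = apply_defaults(run, list(n_runs = 20, base_seed = 1))
  ), class = "scenario_config")
  cfg$workforce$scheduled_hires <- as_scheduled_hires(cfg$workforce$scheduled_hires)
  validate_scenario(cfg)
}

apply_defaults <- function(x, defaults) {
  x <- as.list(x)
  missing <- setdiff(names(defaults), names(x))
  x[missing] <- defaults[missing]
  x
}

as_scheduled_hires <- function(x) {
  if (is.null(x) || (is.list(x) && !is.data.frame(x) && length(x) == 0)) {
    return(data.frame(period = integer(), count = integer()))
  }
  if (is.data.frame(x)) {
    return(data.frame(period = as.numeric(x$period), count = as.numeric(x$count)))
  }
  # list of {period:, count:} maps (YAML form)
  data.frame(
    period = vapply(x, function(h) as.numeric(h$period), numeric(1)),
    count = vapply(x, function(h) as.numeric(h$count), numeric(1))
  )
}

#' Validate a scenario configuration
#'
#' Checks every declared bound (probabilities in \[0,1\], positive standard
#' deviations, non-negative counts, informative score ordering) and fails
#' with an error naming the offending field and bound.
#'
#' @param cfg A `scenario_config` (or a bare list with the same shape).
#' @return The validated `scenario_config`, invisibly usable in pipelines.
#' @export
validate_scenario <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid scenario: field '%s' %s", field, msg), call. = FALSE)
  }
  need_num <- function(block, field) {
    v <- cfg[[block]][[field]]
    if (is.null(v)) fail(paste0(block, ".", field), "is missing")
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      fail(paste0(block, ".", field), "must be a single number")
    }
    v
  }
  check_range <- function(block, field, lo, hi, lo_open = FALSE) {
    v <- need_num(block, field)
    if (v < lo || v > hi || (lo_open && v == lo)) {
      fail(paste0(block, ".", field),
           sprintf("must be in %s%g, %g]", if (lo_open) "(" else "[", lo, hi))
    }
    v
  }

  if (!is.character(cfg$name) || length(cfg$name) != 1 || !nzchar(cfg$name)) {
    fail("name", "must be a non-empty string")
  }
  for (blk in c("population", "instrument", "cascade", "workforce", "queue",
                "feedback", "run")) {
    if (is.null(cfg[[blk]])) fail(blk, "block is missing")
  }

  check_range("population", "prevalence", 0, 1)
  check_range("population", "reach", 0, 1)
  check_range("population", "cohort_inflow_per_period", 0, Inf)
  check_range("population", "n_periods", 1, Inf)
  check_range("population", "periods_per_year", 1, Inf)

  need_num("instrument", "mean_score_negative")
  need_num("instrument", "mean_score_positive")
  check_range("instrument", "sd_score_negative", 0, Inf, lo_open = TRUE)
  check_range("instrument", "sd_score_positive", 0, Inf, lo_open = TRUE)
  need_num("instrument", "threshold")
  if (cfg$instrument$mean_score_positive < cfg$instrument$mean_score_negative) {
    fail("instrument.mean_score_positive",
         "must be >= mean_score_negative (informative screen)")
  }

  for (f in c("p_referral_given_positive_with_condition",
              "p_referral_given_positive_without_condition",
              "p_completion_with_condition",
              "p_completion_without_condition")) {
    check_range("cascade", f, 0, 1)
  }

  check_range("workforce", "initial_providers", 0, Inf)
  check_range("workforce", "slots_per_provider_per_period", 0, Inf, lo_open = TRUE)
  check_range("workforce", "treatment_duration_periods", 1, Inf)
  check_range("workforce", "quit_prob_per_period", 0, 1)
  check_range("workforce", "hires_per_trigger", 0, Inf)
  check_range("workforce", "hiring_lag_periods", 0, Inf)
  need_num("workforce", "hiring_trigger_waitlist_per_provider")
  if (!cfg$workforce$hiring_rule %in% c("none", "reactive", "scheduled")) {
    fail("workforce.hiring_rule", "must be one of 'none', 'reactive', 'scheduled'")
  }
  sh <- cfg$workforce$scheduled_hires
  if (!is.data.frame(sh) || !all(c("period", "count") %in% names(sh))) {
    fail("workforce.scheduled_hires", "must have columns 'period' and 'count'")
  }
  if (nrow(sh) > 0 && (any(sh$period < 1) || any(sh$count < 0))) {
    fail("workforce.scheduled_hires", "periods must be >= 1 and counts >= 0")
  }

  check_range("queue", "waitlist_dropout_prob_per_period", 0, 1)
  check_range("queue", "missed_appointment_prob", 0, 1)
  if (!is.logical(cfg$queue$missed_slot_wasted) ||
      length(cfg$queue$missed_slot_wasted) != 1) {
    fail("queue.missed_slot_wasted", "must be TRUE or FALSE")
  }
  if (!identical(cfg$queue$queue_discipline, "fifo")) {
    fail("queue.queue_discipline", "must be 'fifo'")
  }

  if (!is.logical(cfg$feedback$enabled) || length(cfg$feedback$enabled) != 1) {
    fail("feedback.enabled", "must be TRUE or FALSE")
  }
  check_range("feedback", "wait_scale_periods", 0, Inf, lo_open = TRUE)
  check_range("feedback", "max_referral_suppression", 0, 1)
  check_range("feedback", "max_completion_suppression", 0, 1)
  check_range("feedback", "max_quit_amplification", 0, Inf)

  check_range("run", "n_runs", 1, Inf)
  need_num("run", "base_seed")

  class(cfg) <- "scenario_config"
  cfg
}

#' Read a scenario from a YAML file
#'
#' The document must carry the versioned top-level `schema` key (version 1)
#' and the blocks documented in [scenario_config()]. Optional blocks may be
#' omitted; defaults are applied before validation.
#'
#' @param path Path to a YAML scenario document.
#' @return A validated `scenario_config`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  schema <- doc$schema %||% 1L
  if (!identical(as.integer(schema), 1L)) {
    stop("unsupported scenario schema version: ", schema, call. = FALSE)
  }
  for (key in c("name", "population", "instrument", "cascade", "workforce")) {
    if (is.null(doc[[key]])) {
      stop(sprintf("scenario document missing required key '%s'", key),
           call. = FALSE)
    }
  }
  scenario_config(
    name = doc$name,
    population = doc$population,
    instrument = doc$instrument,
    cascade = doc$cascade,
    workforce = doc$workforce,
    queue = doc$queue %||% list(),
    feedback = doc$feedback %||% list(),
    run = doc$run %||% list()
  )
}

#' Write a scenario to a YAML file
#'
#' `load_scenario(save_scenario(cfg, path))` reproduces `cfg` (numeric values
#' round-trip at 15 significant digits).
#'
#' @param cfg A `scenario_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_scenario <- function(cfg, path) {
  cfg <- validate_scenario(cfg)
  doc <- unclass(cfg)
  sh <- doc$workforce$scheduled_hires
  doc$workforce$scheduled_hires <- if (nrow(sh) == 0) list() else
    lapply(seq_len(nrow(sh)), function(i) list(period = sh$period[i], count = sh$count[i]))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> '%s'\n", x$name))
  cat(sprintf("  population: %g entrants/period, prevalence %.3g, reach %.3g, %d periods\n",
              x$population$cohort_inflow_per_period, x$population$prevalence,
              x$population$reach, as.integer(x$population$n_periods)))
  op <- operating_point(x$instrument)
  cat(sprintf("  instrument: threshold %.3g (Se %.3f, Sp %.3f)\n",
              x$instrument$threshold, op$sensitivity, op$specificity))
  cat(sprintf("  workforce:  %g providers x %g slots, duration %g periods, hiring '%s'\n",
              x$workforce$initial_providers, x$workforce$slots_per_provider_per_period,
              x$workforce$treatment_duration_periods, x$workforce$hiring_rule))
  cat(sprintf("  feedback:   %s; run: %g runs, base seed %g\n",
              if (isTRUE(x$feedback$enabled)) "enabled" else "disabled",
              x$run$n_runs, x$run$base_seed))
  invisible(x)
}

#' Bundled illustrative scenarios
#'
#' `make_baseline_scenario()` describes a statewide system screening children
#' entering foster care for trauma at a recommended instrument cut-score;
#' `make_raised_threshold_scenario()` is identical except for a strictly
#' higher cut-score. Parameter values are illustrative, chosen from plausible
#' published ranges; they are sized so that, at the recommended threshold,
#' expected treatment demand (about 44 referrals completed per month)
#' transiently exceeds initial workforce throughput (about 24 treatment
#' starts per month), so a waitlist builds and peaks within the first two
#' simulated years under reactive hiring with a 3-month lag.
#'
#' @return A `scenario_config`.
#' @export
make_baseline_scenario <- function() {
  scenario_config(
    name = "baseline",
    population = list(
      cohort_inflow_per_period = 200,
      prevalence = 0.40,
      reach = 0.90,
      n_periods = 60,
      periods_per_year = 12
    ),
    instrument = list(
      mean_score_negative = 0,
      mean_score_positive = 1.5,
      sd_score_negative = 1,
      sd_score_positive = 1,
      threshold = 0.5
    ),
    cascade = list(
      p_referral_given_positive_with_condition = 0.8,
      p_referral_given_positive_without_condition = 0.6,
      p_completion_with_condition = 0.7,
      p_completion_without_condition = 0.5
    ),
    workforce = list(
      initial_providers = 6,
      slots_per_provider_per_period = 12,
      treatment_duration_periods = 3,
      quit_prob_per_period = 0.01,
      hiring_rule = "reactive",
      hiring_trigger_waitlist_per_provider = 3,
      hires_per_trigger = 1,
      hiring_lag_periods = 3
    ),
    queue = list(
      waitlist_dropout_prob_per_period = 0.01,
      missed_appointment_prob = 0.05,
      missed_slot_wasted = TRUE
    ),
    run = list(n_runs = 20, base_seed = 42)
  )
}

#' @rdname make_baseline_scenario
#' @export
make_raised_threshold_scenario <- function() {
  cfg <- make_baseline_scenario()
  cfg$name <- "raised_threshold"
  cfg$instrument$threshold <- 1.5
  validate_scenario(cfg)
}
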
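#' Simulate one period's entering cohort through the screening cascade
#'
#' One cohort enters, is split into true condition strata, and flows through
#' screen -> screen-positive -> referral offered -> referral completed by
#' successive binomial thinning. Every stage count is, marginally, binomial
#' in the cohort size with success probability equal to the product of the
#' stage probabilities up to that point, so ensemble means converge to the
#' closed-form chain of [expected_cascade()]. Screen-positives among the
#' with-condition stratum occur with probability `sensitivity`; among the
#' without-condition stratum with probability `1 - specificity`. Referral
#' offer and completion use stratum-specific probabilities (children with
#' and without the condition may differ in their chance of referral and
#' retention).
#'
#' @param cfg A `scenario_config`.
#' @param op An `operating_point` from [operating_point()].
#' @param effective_probs Cascade probabilities after any feedback
#'   adjustment; defaults to `cfg$cascade`.
#' @return A list of class `period_counts` with per-stratum counts
#'   `entered_with`, `screened_with`, `positive_with`, `referred_with`,
#'   `completed_with` and the `_without` analogues. Counts are non-increasing
#'   along each chain by construction.
#' @export
simulate_period_cohort <- function(cfg, op, effective_probs = cfg$cascade) {
  pop <- cfg$population
  n <- pop$cohort_inflow_per_period
  n_with <- stats::rbinom(1, n, pop$prevalence)
  n_without <- n - n_with

  chain <- function(entered, p_screen_pos, p_ref, p_comp) {
    screened <- stats::rbinom(1, entered, pop$reach)
    positive <- stats::rbinom(1, screened, p_screen_pos)
    referred <- stats::rbinom(1, positive, p_ref)
    completed <- stats::rbinom(1, referred, p_comp)
    c(entered = entered, screened = screened, positive = positive,
      referred = referred, completed = completed)
  }

  w <- chain(n_with, op$sensitivity,
             effective_probs$p_referral_given_positive_with_condition,
             effective_probs$p_completion_with_condition)
  wo <- chain(n_without, 1 - op$specificity,
              effective_probs$p_referral_given_positive_without_condition,
              effective_probs$p_completion_without_condition)

  structure(list(
    entered_with = w[["entered"]], screened_with = w[["screened"]],
    positive_with = w[["positive"]], referred_with = w[["referred"]],
    completed_with = w[["completed"]],
    entered_without = wo[["entered"]], screened_without = wo[["screened"]],
    positive_without = wo[["positive"]], referred_without = wo[["referred"]],
    completed_without = wo[["completed"]]
  ), class = "period_counts")
}

#' Deterministic expected counts at every cascade stage
#'
#' The exact expectation of [simulate_period_cohort()]: products of stage
#' probabilities per stratum, with no randomness. Used as the fluid-limit
#' oracle for the Monte-Carlo engine and to size fixture regimes.
#'
#' @param cfg A `scenario_config`.
#' @param op An `operating_point`; defaults to the config's instrument.
#' @return A data frame with columns `stratum` (`"with"`/`"without"`),
#'   `stage` (`entered`, `screened`, `screen_positive`, `referred`,
#'   `completed_referral`) and `expected`.
#' @export
expected_cascade <- function(cfg, op = operating_point(cfg$instrument)) {
  pop <- cfg$population
  cs <- cfg$cascade
  n <- pop$cohort_inflow_per_period
  stage_names <- c("entered", "screened", "screen_positive", "referred",
                   "completed_referral")
  with_chain <- n * pop$prevalence *
    cumprod(c(1, pop$reach, op$sensitivity,
              cs$p_referral_given_positive_with_condition,
              cs$p_completion_with_condition))
  without_chain <- n * (1 - pop$prevalence) *
    cumprod(c(1, pop$reach, 1 - op$specificity,
              cs$p_referral_given_positive_without_condition,
              cs$p_completion_without_condition))
  data.frame(
    stratum = rep(c("with", "without"), each = length(stage_names)),
    stage = rep(stage_names, 2),
    expected = c(with_chain, without_chain)
  )
}
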
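no_misses <- list(queue_discipline = "fifo",
                  waitlist_dropout_prob_per_period = 0,
                  missed_appointment_prob = 0, missed_slot_wasted = TRUE)

wf_base <- function(providers, slots, duration = 1, ...) {
  cfg <- deterministic_scenario(providers = providers, slots = slots,
                                workforce = list(treatment_duration_periods = duration, ...))
  cfg$workforce
}

test_that("new-start capacity is total slots net of continuing caseload", {
  wf <- wf_base(5, 4)
  expect_equal(capacity(new_service_state(wf), wf), 20)
  wf0 <- wf_base(0, 4)
  expect_equal(capacity(new_service_state(wf0), wf0), 0)
})

test_that("capacity agrees with a brute-force slot ledger under duration 3", {
  wf <- wf_base(3, 4, duration = 3)
  q <- no_misses
  state <- new_service_state(wf)
  ledger <- integer(0)  # start period of each treatment episode
  for (t in 1:15) {
    # oracle: an episode started at s occupies a slot at the scheduling step
    # of periods s+1 and s+2 (it completes when period s+3 begins)
    active <- sum(ledger >= t - 2)
    res <- step_service(state, c(with = 5, without = 0), wf, q, period = t)
    expect_equal(res$metrics$capacity, max(0, 12 - active),
                 label = paste("period", t))
    state <- res$state
    ledger <- c(ledger, rep(t, res$metrics$starts_with))
  }
})

test_that("deterministic over- and under-capacity queues follow the fluid limit", {
  wf <- wf_base(2, 4)  # capacity 8
  state <- new_service_state(wf)
  for (t in 1:10) {
    state <- step_service(state, c(with = 10, without = 0), wf, no_misses, t)$state
    expect_equal(sum(state$waitlist$n), 2 * t)
  }
  state <- new_service_state(wf)
  for (t in 1:10) {
    state <- step_service(state, c(with = 5, without = 0), wf, no_misses, t)$state
    expect_equal(sum(state$waitlist$n), 0)
  }
})

test_that("missed appointments waste slots only when configured to", {
  wf <- wf_base(2, 10)  # capacity 20
  q_wasted <- modifyList(no_misses, list(missed_appointment_prob = 0.3))
  q_free <- modifyList(q_wasted, list(missed_slot_wasted = FALSE))

  set.seed(9)
  state <- new_service_state(wf)
  starts <- misses <- 0
  for (t in 1:40) {
    res <- step_service(state, c(with = 50, without = 0), wf, q_wasted, t)
    state <- res$state
    starts <- starts + res$metrics$starts_with
    misses <- misses + res$metrics$misses
  }
  # wasted slots: attempts are capped at capacity, so starts fall short
  expect_equal(starts + misses, 20 * 40)
  expect_gt(misses, 0)

  state <- new_service_state(wf)
  for (t in 1:20) {
    res <- step_service(state, c(with = 50, without = 0), wf, q_free, t)
    state <- res$state
    # a miss frees its slot, so the full capacity is always started
    expect_equal(res$metrics$starts_with, 20)
  }
})

test_that("all-miss periods start nobody and return everyone to the waitlist", {
  wf <- wf_base(1, 5)
  q_all_miss <- modifyList(no_misses, list(missed_appointment_prob = 1))
  state <- new_service_state(wf)
  for (t in 1:5) {
    res <- step_service(state, c(with = 3, without = 1), wf, q_all_miss, t)
    state <- res$state
    expect_equal(res$metrics$starts_with + res$metrics$starts_without, 0)
    expect_equal(sum(state$waitlist$n), 4 * t)
  }
})

test_that("waitlist service is first-in-first-out", {
  wf <- wf_base(1, 3)  # capacity 3, arrivals 5: backlog builds
  state <- new_service_state(wf)
  set.seed(4)
  for (t in 1:12) {
    res <- step_service(state, c(with = 3, without = 2), wf, no_misses, t)
    state <- res$state
    if (nrow(state$waitlist) > 0 &&
        length(res$metrics$start_arrival_periods) > 0) {
      expect_lte(max(res$metrics$start_arrival_periods),
                 min(state$waitlist$arrival_period))
    }
  }
})

test_that("pending hires mature at their availability period and quits remove providers", {
  wf <- wf_base(2, 4, duration = 1,
                hiring_rule = "scheduled",
                scheduled_hires = data.frame(period = 3, count = 2))
  state <- new_service_state(wf)
  for (t in 1:4) {
    res <- step_service(state, c(with = 0, without = 0), wf, no_misses, t)
    state <- res$state
    expect_equal(state$providers, if (t >= 3) 4 else 2)
  }

  wf_quit <- wf_base(5, 4)
  wf_quit$quit_prob_per_period <- 1
  state <- new_service_state(wf_quit)
  state <- step_service(state, c(with = 0, without = 0), wf_quit, no_misses, 1)$state
  expect_equal(state$providers, 0)
})

test_that("reactive hiring orders arrive after the configured lag", {
  wf <- wf_base(1, 2, duration = 1,
                hiring_rule = "reactive",
                hiring_trigger_waitlist_per_provider = 3,
                hires_per_trigger = 2, hiring_lag_periods = 4)
  state <- new_service_state(wf)
  providers <- numeric(0)
  for (t in 1:8) {
    state <- step_service(state, c(with = 6, without = 0), wf, no_misses, t)$state
    providers <- c(providers, state$providers)
  }
  # waitlist (4/period) first exceeds 3x providers at t=1; order matures at t=5
  expect_equal(providers[1:4], rep(1, 4))
  expect_equal(providers[5], 3)
})

test_that("cumulative arrivals are conserved across starts, waitlist and dropouts", {
  for (regime in c("over_capacity", "balanced", "under_capacity")) {
    cfg <- sample_scenario(fixture_spec(regime, seed = 23, n_periods = 20))
    for (tr in run_ensemble(cfg)$trajectories) {
      s <- tr$series
      expect_equal(s$cum_arrivals, s$cum_starts + s$waitlist + s$cum_dropouts,
                   label = paste(regime, "run", tr$run_index))
    }
  }
})

test_that("feedback multipliers are identity at zero wait and half-effect at the scale wait", {
  fb <- list(enabled = TRUE, wait_scale_periods = 6,
             max_referral_suppression = 0.4, max_completion_suppression = 0.6,
             max_quit_amplification = 2)
  wf <- wf_base(1, 1)
  wf$quit_prob_per_period <- 0.02
  base <- list(p_referral_given_positive_with_condition = 0.8,
               p_referral_given_positive_without_condition = 0.6,
               p_completion_with_condition = 0.7,
               p_completion_without_condition = 0.5)

  state <- new_service_state(wf)  # empty waitlist, capacity 1
  eff0 <- apply_feedback(state, fb, base, wf)
  expect_equal(eff0$cascade, base)
  expect_equal(eff0$quit_prob, 0.02)

  # waitlist of 6 with capacity 1 gives expected wait w = scale, so f = 1/2
  state$waitlist <- data.frame(arrival_period = 1, status = "with", n = 6,
                               stringsAsFactors = FALSE)
  eff <- apply_feedback(state, fb, base, wf)
  expect_equal(eff$cascade$p_completion_with_condition, 0.7 * (1 - 0.5 * 0.6))
  expect_equal(eff$cascade$p_referral_given_positive_with_condition,
               0.8 * (1 - 0.5 * 0.4))
  expect_equal(eff$quit_prob, 0.02 * 2)

  fb$enabled <- FALSE
  expect_equal(apply_feedback(state, fb, base, wf)$cascade, base)
})
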
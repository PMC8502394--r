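#' Initial state of the treatment service system
#'
#' The state tracks the FIFO waitlist (grouped by arrival period and true
#' condition status), the in-treatment census bucketed by remaining
#' duration, the provider count, pending hire orders, and cumulative
#' bookkeeping used by the conservation invariant
#' (arrivals = treatment starts + current waitlist + dropouts).
#'
#' @param wf Workforce parameter list (see [scenario_config()]). Under the
#'   scheduled hiring rule the `scheduled_hires` table is preloaded as
#'   pending hires maturing at the listed periods.
#' @return A list of class `service_state`.
#' @export
new_service_state <- function(wf) {
  pending <- data.frame(available_period = numeric(), n = numeric())
  if (identical(wf$hiring_rule, "scheduled") && nrow(wf$scheduled_hires) > 0) {
    sh <- wf$scheduled_hires
    pending <- data.frame(available_period = sh$period, n = sh$count)
    pending <- pending[order(pending$available_period), , drop = FALSE]
  }
  structure(list(
    waitlist = data.frame(arrival_period = numeric(), status = character(),
                          n = numeric(), stringsAsFactors = FALSE),
    in_treatment = rep(0, wf$treatment_duration_periods),
    providers = wf$initial_providers,
    pending_hires = pending,
    cumulative_treated = c(with = 0, without = 0),
    cumulative_dropouts = 0,
    cumulative_arrivals = 0
  ), class = "service_state")
}

#' Treatment starts the workforce can absorb this period
#'
#' Each provider carries `slots_per_provider_per_period` concurrent cases;
#' continuing treatments occupy slots until they complete, so new-start
#' capacity is the total slot count net of the continuing caseload, floored
#' at zero.
#'
#' @param state A `service_state`.
#' @param wf Workforce parameters.
#' @return Non-negative count of possible new treatment starts.
#' @export
capacity <- function(state, wf) {
  max(0, state$providers * wf$slots_per_provider_per_period -
        sum(state$in_treatment))
}

waitlist_length <- function(state) sum(state$waitlist$n)

#' Advance the service system by one period
#'
#' The within-period event order is fixed:
#' 1. pending hires maturing this period join the provider pool;
#' 2. provider quits are drawn Binomial(providers, quit_prob);
#' 3. treatments in progress advance one period; completions release slots;
#' 4. waitlist dropout is drawn per waiting person;
#' 5. the period's arrivals join the waitlist tail;
#' 6. up to [capacity()] waitlist entries are scheduled FIFO; each scheduled
#'    start misses with probability `missed_appointment_prob` — when
#'    `missed_slot_wasted` the miss consumes the slot for this period and the
#'    person returns to the head of the waitlist (exempt from strict FIFO);
#' 7. under the reactive rule, a hire order for `hires_per_trigger`
#'    providers is placed whenever the post-step waitlist-to-provider ratio
#'    exceeds the trigger, maturing `hiring_lag_periods` later. Orders are
#'    never cancelled.
#'
#' When a scheduling batch cuts partway through a group of people who joined
#' the waitlist in the same period, the split between true-status strata is
#' hypergeometric (people within a period are in random order).
#'
#' @param state A `service_state`.
#' @param arrivals Named count vector `c(with = , without = )` of completed
#'   referrals arriving this period.
#' @param wf Workforce parameters.
#' @param q Queue parameters.
#' @param period Current period index (1-based).
#' @param quit_prob Effective per-provider quit probability (defaults to the
#'   workforce parameter; feedback may amplify it).
#' @return A list with the new `state` and a `metrics` list: `period`,
#'   `waitlist_length`, `capacity` (pre-start), `providers`, `starts_with`,
#'   `starts_without`, `misses`, `dropouts`, `quits`, `hires_matured`, and
#'   `start_arrival_periods` (arrival periods of this period's successful
#'   starts, for FIFO auditing).
#' @export
step_service <- function(state, arrivals, wf, q, period,
                         quit_prob = wf$quit_prob_per_period) {
  # 1. hires mature
  mature <- state$pending_hires$available_period <= period
  hires_matured <- sum(state$pending_hires$n[mature])
  state$providers <- state$providers + hires_matured
  state$pending_hires <- state$pending_hires[!mature, , drop = FALSE]

  # 2. quits
  quits <- stats::rbinom(1, state$providers, quit_prob)
  state$providers <- state$providers - quits

  # 3. progress; completions release slots
  state$in_treatment <- c(state$in_treatment[-1], 0)

  # 4. waitlist dropout
  dropouts <- 0
  if (nrow(state$waitlist) > 0 && q$waitlist_dropout_prob_per_period > 0) {
    gone <- stats::rbinom(nrow(state$waitlist), state$waitlist$n,
                          q$waitlist_dropout_prob_per_period)
    dropouts <- sum(gone)
    state$waitlist$n <- state$waitlist$n - gone
    state$waitlist <- state$waitlist[state$waitlist$n > 0, , drop = FALSE]
  }
  state$cumulative_dropouts <- state$cumulative_dropouts + dropouts

  # 5. arrivals join the tail
  state$cumulative_arrivals <- state$cumulative_arrivals + sum(arrivals)
  for (st in c("with", "without")) {
    if (arrivals[[st]] > 0) {
      state$waitlist <- rbind(state$waitlist, data.frame(
        arrival_period = period, status = st, n = as.numeric(arrivals[[st]]),
        stringsAsFactors = FALSE))
    }
  }

  # 6. FIFO starts with missed appointments
  cap <- capacity(state, wf)
  res <- schedule_starts(state$waitlist, cap, q)
  state$waitlist <- res$waitlist
  state$in_treatment[wf$treatment_duration_periods] <-
    state$in_treatment[wf$treatment_duration_periods] + res$starts[["with"]] +
    res$starts[["without"]]
  state$cumulative_treated <- state$cumulative_treated + res$starts

  # 7. reactive hiring on post-step ratio
  if (identical(wf$hiring_rule, "reactive")) {
    ratio <- waitlist_length(state) / max(state$providers, 1)
    if (ratio > wf$hiring_trigger_waitlist_per_provider &&
        wf$hires_per_trigger > 0) {
      state$pending_hires <- rbind(state$pending_hires, data.frame(
        available_period = period + wf$hiring_lag_periods,
        n = wf$hires_per_trigger))
    }
  }

  list(state = state, metrics = list(
    period = period,
    waitlist_length = waitlist_length(state),
    capacity = cap,
    providers = state$providers,
    starts_with = res$starts[["with"]],
    starts_without = res$starts[["without"]],
    misses = res$misses,
    dropouts = dropouts,
    quits = quits,
    hires_matured = hires_matured,
    start_arrival_periods = res$start_arrival_periods
  ))
}

# Pull FIFO blocks (people sharing an arrival period) off the waitlist head,
# draw misses, and return the updated waitlist with miss-returns prepended at
# the head. When a scheduling batch cuts partway through a block the split
# between strata is hypergeometric (random order within a period).
schedule_starts <- function(wl, cap, q) {
  m <- q$missed_appointment_prob
  wl_row <- function(period, status, n) {
    data.frame(arrival_period = period, status = status, n = n,
               stringsAsFactors = FALSE)
  }
  starts <- c(with = 0, without = 0)
  misses <- 0
  start_arrivals <- numeric(0)
  returned <- wl[0, , drop = FALSE]

  if (m == 0 || isTRUE(q$missed_slot_wasted)) {
    # every scheduled person consumes one slot, miss or not
    slots <- cap
    while (slots > 0 && nrow(wl) > 0) {
      hp <- wl$arrival_period[1]
      sel <- wl$arrival_period == hp
      n_w <- sum(wl$n[sel & wl$status == "with"])
      n_wo <- sum(wl$n[sel & wl$status == "without"])
      k <- min(slots, n_w + n_wo)
      k_w <- if (k == n_w + n_wo) n_w else stats::rhyper(1, n_w, n_wo, k)
      k_wo <- k - k_w
      mi_w <- if (m > 0) stats::rbinom(1, k_w, m) else 0
      mi_wo <- if (m > 0) stats::rbinom(1, k_wo, m) else 0
      starts <- starts + c(with = k_w - mi_w, without = k_wo - mi_wo)
      misses <- misses + mi_w + mi_wo
      start_arrivals <- c(start_arrivals, rep(hp, k - mi_w - mi_wo))
      slots <- slots - k
      wl <- wl[!sel, , drop = FALSE]
      if (n_wo - k_wo > 0) wl <- rbind(wl_row(hp, "without", n_wo - k_wo), wl)
      if (n_w - k_w > 0) wl <- rbind(wl_row(hp, "with", n_w - k_w), wl)
      if (mi_w > 0) returned <- rbind(returned, wl_row(hp, "with", mi_w))
      if (mi_wo > 0) returned <- rbind(returned, wl_row(hp, "without", mi_wo))
    }
  } else {
    # a miss frees the slot for the next person; each waiting person is
    # attempted at most once per period
    need <- cap
    while (need > 0 && nrow(wl) > 0) {
      hp <- wl$arrival_period[1]
      sel <- wl$arrival_period == hp
      n_w <- sum(wl$n[sel & wl$status == "with"])
      n_wo <- sum(wl$n[sel & wl$status == "without"])
      st <- if (stats::runif(1) < n_w / (n_w + n_wo)) "with" else "without"
      if (stats::runif(1) < m) {
        misses <- misses + 1
        returned <- rbind(returned, wl_row(hp, st, 1))
      } else {
        starts[[st]] <- starts[[st]] + 1
        start_arrivals <- c(start_arrivals, hp)
        need <- need - 1
      }
      if (st == "with") n_w <- n_w - 1 else n_wo <- n_wo - 1
      wl <- wl[!sel, , drop = FALSE]
      if (n_wo > 0) wl <- rbind(wl_row(hp, "without", n_wo), wl)
      if (n_w > 0) wl <- rbind(wl_row(hp, "with", n_w), wl)
    }
  }

  # merge duplicate rows in the returned buffer before prepending
  if (nrow(returned) > 1) {
    agg <- stats::aggregate(n ~ arrival_period + status, data = returned, sum)
    agg <- agg[order(agg$arrival_period), , drop = FALSE]
    returned <- agg[, c("arrival_period", "status", "n"), drop = FALSE]
  }
  list(waitlist = rbind(returned, wl), starts = starts, misses = misses,
       start_arrival_periods = start_arrivals)
}

#' Waitlist feedback on cascade probabilities and provider quits
#'
#' Long waits feed back on the system: referral offers and referral
#' completion are suppressed, and provider quits amplified, as the expected
#' wait grows. The expected wait is approximated Little's-law style as
#' `w = waitlist_length / max(capacity, 1)` periods, and the effect follows
#' a saturating multiplier `f(w) = w / (w + wait_scale_periods)` in \[0, 1):
#' referral and completion probabilities are scaled by
#' `1 - max_*_suppression * f(w)` and the quit probability by
#' `1 + max_quit_amplification * f(w)` (capped at 1). With feedback disabled
#' the identity is returned.
#'
#' @param state A `service_state`.
#' @param fb Feedback parameters.
#' @param base Baseline cascade probabilities.
#' @param wf Workforce parameters.
#' @return A list with elements `cascade` (effective probabilities) and
#'   `quit_prob`.
#' @export
apply_feedback <- function(state, fb, base, wf) {
  if (!isTRUE(fb$enabled)) {
    return(list(cascade = base, quit_prob = wf$quit_prob_per_period))
  }
  w <- waitlist_length(state) / max(capacity(state, wf), 1)
  f <- w / (w + fb$wait_scale_periods)
  ref_mult <- 1 - fb$max_referral_suppression * f
  comp_mult <- 1 - fb$max_completion_suppression * f
  eff <- base
  eff$p_referral_given_positive_with_condition <-
    base$p_referral_given_positive_with_condition * ref_mult
  eff$p_referral_given_positive_without_condition <-
    base$p_referral_given_positive_without_condition * ref_mult
  eff$p_completion_with_condition <-
    base$p_completion_with_condition * comp_mult
  eff$p_completion_without_condition <-
    base$p_completion_without_condition * comp_mult
  list(cascade = eff,
       quit_prob = min(1, wf$quit_prob_per_period *
                         (1 + fb$max_quit_amplification * f)))
}
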
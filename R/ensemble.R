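#' Simulate one seeded trajectory of the full system
#'
#' Runs the screening cascade and the treatment service system forward for
#' `n_periods`, applying waitlist feedback (when enabled) to the cascade
#' probabilities and the quit probability at the start of each period, then
#' simulating the period's cohort and stepping the queue/workforce.
#'
#' @param cfg A `scenario_config`.
#' @param seed Integer seed for this run's random number stream.
#' @param run_index Index of the run within its ensemble (bookkeeping only).
#' @return A list of class `run_trajectory` with `run_index`, `seed` and
#'   `series`, a data frame with one row per period: the cascade stage counts
#'   per stratum, `arrivals` (completed referrals), service metrics
#'   (`waitlist`, `capacity`, `providers`, `starts`, `misses`, `dropouts`,
#'   `quits`) and cumulative counts (`cum_entered_with`, `cum_entered_without`,
#'   `cum_treated_with`, `cum_treated_without`, `cum_arrivals`,
#'   `cum_dropouts`, `cum_starts`).
#' @export
run_trajectory <- function(cfg, seed = cfg$run$base_seed, run_index = 1L) {
  set.seed(seed)
  op <- operating_point(cfg$instrument)
  state <- new_service_state(cfg$workforce)
  n_periods <- cfg$population$n_periods
  rows <- vector("list", n_periods)

  for (t in seq_len(n_periods)) {
    eff <- apply_feedback(state, cfg$feedback, cfg$cascade, cfg$workforce)
    pc <- simulate_period_cohort(cfg, op, eff$cascade)
    arrivals <- c(with = pc$completed_with, without = pc$completed_without)
    res <- step_service(state, arrivals, cfg$workforce, cfg$queue,
                        period = t, quit_prob = eff$quit_prob)
    state <- res$state
    mt <- res$metrics
    rows[[t]] <- data.frame(
      period = t,
      entered_with = pc$entered_with, screened_with = pc$screened_with,
      positive_with = pc$positive_with, referred_with = pc$referred_with,
      completed_with = pc$completed_with,
      entered_without = pc$entered_without, screened_without = pc$screened_without,
      positive_without = pc$positive_without, referred_without = pc$referred_without,
      completed_without = pc$completed_without,
      arrivals = sum(arrivals),
      waitlist = mt$waitlist_length,
      capacity = mt$capacity,
      providers = mt$providers,
      starts = mt$starts_with + mt$starts_without,
      starts_with = mt$starts_with,
      starts_without = mt$starts_without,
      misses = mt$misses,
      dropouts = mt$dropouts,
      quits = mt$quits,
      cum_treated_with = state$cumulative_treated[["with"]],
      cum_treated_without = state$cumulative_treated[["without"]],
      cum_arrivals = state$cumulative_arrivals,
      cum_dropouts = state$cumulative_dropouts
    )
  }
  series <- do.call(rbind, rows)
  series$cum_entered_with <- cumsum(series$entered_with)
  series$cum_entered_without <- cumsum(series$entered_without)
  series$cum_starts <- cumsum(series$starts)
  structure(list(run_index = run_index, seed = seed, series = series),
            class = "run_trajectory")
}

summary_metric_cols <- c("arrivals", "waitlist", "capacity", "providers",
                         "starts", "cum_treated_with", "cum_treated_without")

#' Run a seeded ensemble and summarize it
#'
#' Runs `cfg$run$n_runs` trajectories with seeds `base_seed + i - 1`
#' (identical config and seed give identical output) and summarizes each
#' metric per period with the across-run mean — the darkened average line
#' over the fan of individual trajectories — plus the min/max envelope.
#'
#' @param cfg A `scenario_config`.
#' @return A list of class `ensemble_result` with `trajectories` (list of
#'   `run_trajectory`), `summary` (data frame: `period`, `metric`, `mean`,
#'   `min`, `max`) and `n_runs`.
#' @export
run_ensemble <- function(cfg) {
  n_runs <- cfg$run$n_runs
  seeds <- cfg$run$base_seed + seq_len(n_runs) - 1
  trajectories <- lapply(seq_len(n_runs), function(i) {
    run_trajectory(cfg, seed = seeds[i], run_index = i)
  })
  summary <- summarize_ensemble(trajectories)
  structure(list(trajectories = trajectories, summary = summary,
                 n_runs = n_runs), class = "ensemble_result")
}

summarize_ensemble <- function(trajectories) {
  n_periods <- nrow(trajectories[[1]]$series)
  rows <- lapply(summary_metric_cols, function(metric) {
    mat <- vapply(trajectories, function(tr) tr$series[[metric]],
                  numeric(n_periods))
    mat <- matrix(mat, nrow = n_periods)
    data.frame(period = seq_len(n_periods), metric = metric,
               mean = rowMeans(mat),
               min = apply(mat, 1, min),
               max = apply(mat, 1, max))
  })
  do.call(rbind, rows)
}

#' @export
print.ensemble_result <- function(x, ...) {
  wl <- x$summary[x$summary$metric == "waitlist", ]
  cat(sprintf("<ensemble_result> %d runs x %d periods\n", x$n_runs, nrow(wl)))
  cat(sprintf("  mean waitlist: peak %.1f at period %d, final %.1f\n",
              max(wl$mean), which.max(wl$mean), wl$mean[nrow(wl)]))
  invisible(x)
}

#' Process-level performance metrics of one trajectory
#'
#' Process sensitivity is the probability that a child who truly has the
#' condition is ultimately treated — compounding screen accuracy, referral,
#' completion, and capacity attrition — as opposed to the sensitivity of the
#' screener alone. Process specificity is the probability that a child
#' without the condition is not treated.
#'
#' @param traj A `run_trajectory`.
#' @return A list with `process_sensitivity` (treated-with / entered-with),
#'   `process_specificity` (1 - treated-without / entered-without),
#'   `fp_treated_fraction` (share of all treatment starts that are
#'   without-condition children) and `undefined`, a character vector naming
#'   metrics whose denominator was zero (their value is `NA`, never 0/0).
#' @export
process_metrics <- function(traj) {
  s <- traj$series
  last <- nrow(s)
  entered_w <- s$cum_entered_with[last]
  entered_wo <- s$cum_entered_without[last]
  treated_w <- s$cum_treated_with[last]
  treated_wo <- s$cum_treated_without[last]
  undefined <- character(0)
  sens <- if (entered_w > 0) treated_w / entered_w else {
    undefined <- c(undefined, "process_sensitivity"); NA_real_
  }
  spec <- if (entered_wo > 0) 1 - treated_wo / entered_wo else {
    undefined <- c(undefined, "process_specificity"); NA_real_
  }
  fp <- if (treated_w + treated_wo > 0) treated_wo / (treated_w + treated_wo) else {
    undefined <- c(undefined, "fp_treated_fraction"); NA_real_
  }
  list(process_sensitivity = sens, process_specificity = spec,
       fp_treated_fraction = fp, undefined = undefined)
}

ensemble_metrics_row <- function(ens) {
  pm <- lapply(ens$trajectories, process_metrics)
  mean_def <- function(field) {
    v <- vapply(pm, function(p) p[[field]], numeric(1))
    mean(v, na.rm = TRUE)
  }
  terminal <- function(col) {
    mean(vapply(ens$trajectories,
                function(tr) tr$series[[col]][nrow(tr$series)], numeric(1)))
  }
  wl <- ens$summary[ens$summary$metric == "waitlist", ]
  data.frame(
    process_sensitivity = mean_def("process_sensitivity"),
    process_specificity = mean_def("process_specificity"),
    fp_treated = terminal("cum_treated_without"),
    mean_waitlist = mean(wl$mean),
    peak_waitlist = max(wl$mean),
    cum_treated_with = terminal("cum_treated_with")
  )
}

#' Sweep a numeric scenario parameter under common random numbers
#'
#' Re-runs the ensemble at each grid value with identical per-run seeds
#' (common random numbers), so differences between grid points reflect the
#' parameter change rather than sampling noise.
#'
#' @param cfg A `scenario_config`.
#' @param param_path Dotted path to a numeric scalar, e.g.
#'   `"instrument.threshold"` or `"population.reach"`.
#' @param values Strictly increasing numeric grid.
#' @return A data frame with one row per grid value: the parameter value,
#'   ensemble-mean process sensitivity/specificity, false-positive treated
#'   count, mean and peak of the mean waitlist trajectory, and cumulative
#'   treated with-condition children.
#' @export
parameter_sweep <- function(cfg, param_path, values) {
  if (length(values) < 1) stop("empty sweep grid", call. = FALSE)
  if (is.unsorted(values, strictly = TRUE)) {
    stop("sweep grid must be strictly increasing", call. = FALSE)
  }
  rows <- lapply(values, function(v) {
    cfg_v <- set_scenario_value(cfg, param_path, v)
    ens <- run_ensemble(cfg_v)
    cbind(data.frame(value = v), ensemble_metrics_row(ens))
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- gsub(".*\\.", "", param_path)
  out
}

#' Screening threshold sweep
#'
#' The headline virtual experiment: raising the cut-score shortens waitlists
#' but treats fewer children with the condition. Each grid point reports the
#' instrument operating point alongside the ensemble process metrics, under
#' common random numbers.
#'
#' @param cfg A `scenario_config`.
#' @param grid Strictly increasing threshold values.
#' @return A data frame of class `sweep_result`: `threshold`, `sensitivity`,
#'   `specificity` (instrument), plus the columns of [parameter_sweep()].
#' @export
threshold_sweep <- function(cfg, grid) {
  out <- parameter_sweep(cfg, "instrument.threshold", grid)
  ops <- lapply(grid, function(th) {
    inst <- cfg$instrument
    inst$threshold <- th
    operating_point(inst)
  })
  out <- cbind(
    data.frame(threshold = grid,
               sensitivity = vapply(ops, `[[`, numeric(1), "sensitivity"),
               specificity = vapply(ops, `[[`, numeric(1), "specificity")),
    out[, setdiff(names(out), "threshold"), drop = FALSE]
  )
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Hiring-lag experiment
#'
#' Compares reactive hiring under different order-to-onboarding lags with
#' common random numbers. Waiting for demand to rise before providers are
#' onboarded lets the waitlist build before supply catches up with demand,
#' so the ensemble-mean peak waitlist is non-decreasing in the lag.
#'
#' @param cfg A `scenario_config` with `hiring_rule = "reactive"`.
#' @param lags Non-negative lags (periods) to compare.
#' @return A data frame: `lag`, `peak_waitlist` and `peak_period` (max and
#'   argmax of the ensemble-mean waitlist), and `time_to_balance` (first
#'   period with mean capacity >= mean arrivals sustained for 3 consecutive
#'   periods, `NA` if never).
#' @export
hiring_lag_experiment <- function(cfg, lags) {
  if (!identical(cfg$workforce$hiring_rule, "reactive")) {
    stop("hiring_lag_experiment requires hiring_rule = 'reactive'",
         call. = FALSE)
  }
  rows <- lapply(lags, function(lag) {
    cfg_l <- set_scenario_value(cfg, "workforce.hiring_lag_periods", lag)
    ens <- run_ensemble(cfg_l)
    wl <- ens$summary[ens$summary$metric == "waitlist", ]
    cap <- ens$summary[ens$summary$metric == "capacity", "mean"]
    arr <- ens$summary[ens$summary$metric == "arrivals", "mean"]
    data.frame(lag = lag,
               peak_waitlist = max(wl$mean),
               peak_period = which.max(wl$mean),
               time_to_balance = time_to_balance(cap, arr))
  })
  do.call(rbind, rows)
}

# first period where capacity >= demand, sustained `sustain` periods
time_to_balance <- function(capacity, arrivals, sustain = 3) {
  ok <- capacity >= arrivals
  run <- rle(ok)
  ends <- cumsum(run$lengths)
  hit <- which(run$values & run$lengths >= sustain)
  if (length(hit) == 0) return(NA_integer_)
  ends[hit[1]] - run$lengths[hit[1]] + 1L
}

# set a numeric scalar addressed by a dotted path, failing on unknown paths
set_scenario_value <- function(cfg, param_path, value) {
  keys <- strsplit(param_path, ".", fixed = TRUE)[[1]]
  node <- cfg
  for (k in keys) {
    if (is.null(node[[k]])) {
      stop(sprintf("unknown parameter path '%s'", param_path), call. = FALSE)
    }
    node <- node[[k]]
  }
  cfg[[keys]] <- value
  validate_scenario(cfg)
}
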
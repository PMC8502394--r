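test_that("identical config and seed reproduce trajectories exactly", {
  cfg <- ample_capacity_scenario(n_runs = 3)
  a <- run_ensemble(cfg)
  b <- run_ensemble(cfg)
  for (i in seq_len(3)) {
    expect_identical(a$trajectories[[i]]$series, b$trajectories[[i]]$series)
  }
  expect_identical(a$summary, b$summary)
})

test_that("a fully deterministic config has a zero-width envelope", {
  cfg <- deterministic_scenario(arrivals = 10, providers = 2, slots = 4,
                                n_runs = 5)
  ens <- run_ensemble(cfg)
  expect_equal(ens$n_runs, 5)
  expect_equal(ens$summary$min, ens$summary$max)
  expect_equal(ens$summary$mean, ens$summary$min)
})

test_that("the envelope always contains the mean", {
  cfg <- ample_capacity_scenario(n_runs = 5)
  s <- run_ensemble(cfg)$summary
  expect_true(all(s$min <= s$mean + 1e-12 & s$mean <= s$max + 1e-12))
})

test_that("process sensitivity is 1 when every stage is certain and capacity ample", {
  cfg <- deterministic_scenario(arrivals = 10, providers = 5, slots = 10)
  pm <- process_metrics(run_trajectory(cfg))
  expect_equal(pm$process_sensitivity, 1)
  expect_equal(pm$fp_treated_fraction, 0)
  # prevalence is 1 here, so no condition-negative entrants ever arrive and
  # process specificity is flagged undefined rather than computed as 0/0
  expect_equal(pm$undefined, "process_specificity")
  expect_true(is.na(pm$process_specificity))
})

test_that("zero denominators flag metrics as undefined instead of dividing", {
  cfg <- deterministic_scenario(arrivals = 10)
  cfg$population$prevalence <- 0  # nobody has the condition
  cfg$instrument$threshold <- 30  # and nobody screens positive
  pm <- process_metrics(run_trajectory(cfg))
  expect_true(is.na(pm$process_sensitivity))
  expect_true("process_sensitivity" %in% pm$undefined)
  expect_true("fp_treated_fraction" %in% pm$undefined)
  expect_equal(pm$process_specificity, 1)
})

test_that("halving reach halves process sensitivity when nothing else attrites", {
  cfg <- deterministic_scenario(arrivals = 400, providers = 40, slots = 20,
                                n_periods = 8, n_runs = 6)
  cfg$population$reach <- 0.5
  ens <- run_ensemble(cfg)
  se <- vapply(ens$trajectories,
               function(tr) process_metrics(tr)$process_sensitivity,
               numeric(1))
  # ~5 SE of the pooled binomial estimate (n = 400 x 8 x 6 entrants)
  expect_lt(abs(mean(se) - 0.5), 0.02)
})

test_that("process sensitivity never beats the reach x instrument-sensitivity ceiling", {
  for (seed in c(2, 8)) {
    cfg <- sample_scenario(fixture_spec("under_capacity", seed = seed,
                                        n_periods = 15))
    op <- operating_point(cfg$instrument)
    ens <- run_ensemble(cfg)
    se <- mean(vapply(ens$trajectories,
                      function(tr) process_metrics(tr)$process_sensitivity,
                      numeric(1)))
    expect_lte(se, cfg$population$reach * op$sensitivity + 0.02)
  }
})

test_that("a single-point sweep reproduces the plain ensemble summary", {
  cfg <- ample_capacity_scenario(n_runs = 4)
  sw <- threshold_sweep(cfg, grid = cfg$instrument$threshold)
  ens <- run_ensemble(cfg)
  wl <- ens$summary[ens$summary$metric == "waitlist", ]
  expect_equal(nrow(sw), 1)
  expect_equal(sw$peak_waitlist, max(wl$mean))
  expect_equal(sw$cum_treated_with,
               mean(vapply(ens$trajectories, function(tr)
                 tr$series$cum_treated_with[nrow(tr$series)], numeric(1))))
  op <- operating_point(cfg$instrument)
  expect_equal(sw$sensitivity, op$sensitivity)
})

test_that("a wide-open threshold drives process sensitivity to the referral chain value", {
  cfg <- ample_capacity_scenario(n_periods = 8, n_runs = 5, threshold = -30)
  ens <- run_ensemble(cfg)
  se <- mean(vapply(ens$trajectories,
                    function(tr) process_metrics(tr)$process_sensitivity,
                    numeric(1)))
  # screen passes everyone: reach * p_referral_with * p_completion_with
  expect_equal(se, 0.9 * 0.8 * 0.9, tolerance = 0.03)
})

test_that("sweep grids must be strictly increasing and parameter paths must exist", {
  cfg <- ample_capacity_scenario()
  expect_error(threshold_sweep(cfg, c(1, 0.5)), "increasing")
  expect_error(parameter_sweep(cfg, "unknown.param", 1:3), "unknown.param")
})

test_that("without a hiring rule the workforce only shrinks by quits", {
  cfg <- deterministic_scenario(arrivals = 20, providers = 4, slots = 3,
                                n_periods = 15)
  tr <- run_trajectory(cfg)
  expect_equal(tr$series$providers, rep(4, 15))

  cfg$workforce$quit_prob_per_period <- 0.3
  tr2 <- run_trajectory(cfg, seed = 5)
  expect_true(all(diff(tr2$series$providers) <= 0))
})

test_that("hiring-lag experiment demands a reactive rule", {
  cfg <- deterministic_scenario()
  expect_error(hiring_lag_experiment(cfg, c(0, 3)), "reactive")
})

test_that("time to balance is the first sustained capacity-meets-demand period", {
  cap <- c(10, 2, 2, 5, 5, 5, 5)
  arr <- rep(4, 7)
  expect_equal(screenflow:::time_to_balance(cap, arr), 4L)
  expect_true(is.na(screenflow:::time_to_balance(rep(1, 5), rep(4, 5))))
})
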
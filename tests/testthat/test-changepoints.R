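test_that("stride-1 scan equals the exhaustive brute-force oracle", {
  y <- sim_ar_path(400, b0 = 10, b1 = 0.5, noise_sd = 3, seed = 61)
  pairs <- make_pairs(y)
  cfg <- detector_config(min_segment = 30)
  win <- c(min(pairs$t), max(pairs$t) + 1)
  g <- fit_tv_ar(pairs, cfg)
  scan <- search_best_cp(pairs, win, cfg, gradual = g)
  bf <- brute_force_cp(pairs, win, cfg, g)
  expect_identical(scan$cp_epoch, bf$cp_epoch)
  expect_lt(abs(scan$delta_aic - bf$delta_aic), 1e-6)

  # stride > 1 equals brute force restricted to the strided candidate subset
  cfg5 <- detector_config(min_segment = 30, candidate_stride = 5)
  scan5 <- search_best_cp(pairs, win, cfg5, gradual = g)
  sub <- bf$cand[seq(1, length(bf$cand), by = 5)]
  dd5 <- bf$dd[match(sub, bf$cand)]
  expect_identical(scan5$cp_epoch, sub[which.min(dd5)])
  expect_lt(abs(scan5$delta_aic - min(dd5)), 1e-6)
  expect_gte(scan5$delta_aic, bf$delta_aic - 1e-6)   # approximation gap one-sided
})

test_that("windows too short for two regimes yield no candidate", {
  y <- sim_ar_path(80, b0 = 10, b1 = 0.4, noise_sd = 3, seed = 62)
  pairs <- make_pairs(y)
  cfg <- detector_config(min_segment = 50)
  expect_null(search_best_cp(pairs, config = cfg))
})

test_that("a single strong change point is located accurately", {
  mu1 <- 40; mu2 <- 64                          # level jump = 3 * noise_sd
  regs <- list(regime_spec(0, mu1 * (1 - 0.3), 0.3),
               regime_spec(3000, mu2 * (1 - 0.8), 0.8))
  hits <- 0
  for (seed in 71:73) {
    sim <- simulate_stress_series(regs, missing = missingness_spec(0, 0, 1, 0),
                                  n_days = 12.5, noise_sd = 8, seed = seed)
    pairs <- build_lag_pairs(modeling_view(sim$series))
    res <- search_best_cp(pairs, config = detector_config())
    hits <- hits + (res$delta_aic < -15 && abs(res$cp_epoch - 3000) <= 50)
  }
  expect_equal(hits, 3)
})

test_that("greedy pruning drops clustered and boundary change points", {
  cfg <- detector_config(min_gap = 50, boundary_margin = 50)
  cps <- data.frame(epoch = c(100L, 105L), delta_aic = c(-40, -20))
  pr <- prune_change_points(cps, cfg, series_range = c(0, 1000))
  expect_equal(pr$accepted$epoch, 100L)          # stronger of the pair wins
  expect_equal(pr$excluded$epoch, 105L)
  expect_equal(pr$excluded$reason, "too_close")

  pr2 <- prune_change_points(data.frame(epoch = 3L, delta_aic = -60), cfg,
                             series_range = c(0, 1000))
  expect_equal(nrow(pr2$accepted), 0)
  expect_equal(pr2$excluded$reason, "boundary")

  # a cluster of five within one min_gap collapses to exactly one
  cl <- data.frame(epoch = c(300L, 310L, 315L, 330L, 340L),
                   delta_aic = c(-28, -35, -54, -25, -56))
  pr3 <- prune_change_points(cl, cfg, series_range = c(0, 1000))
  expect_equal(nrow(pr3$accepted), 1)
  expect_equal(pr3$accepted$epoch, 340L)         # most negative delta first
  expect_true(all(pr3$excluded$reason == "too_close"))
})

test_that("recursive detection recovers two well-separated change points", {
  regs <- list(regime_spec(0, 40 * 0.65, 0.35),
               regime_spec(2000, 60 * 0.25, 0.75),
               regime_spec(4000, 35 * 0.6, 0.4))
  sim <- simulate_stress_series(regs, missing = missingness_spec(0, 0, 1, 0),
                                n_days = 12.5, noise_sd = 8, seed = 81)
  cpset <- detect_change_points(sim$series)
  expect_equal(n_change_points(cpset), 2)
  expect_lt(abs(cpset$cps$epoch[1] - 2000), 50)
  expect_lt(abs(cpset$cps$epoch[2] - 4000), 50)
  expect_true(all(cpset$cps$delta_aic < -15))
  expect_equal(nrow(cpset$regimes), 3)
  # regimes partition the analyzed window
  expect_equal(cpset$regimes$start[-1], cpset$cps$epoch)
  expect_equal(cpset$regimes$end[-nrow(cpset$regimes)], cpset$cps$epoch)
  # determinism: no randomness in the detector
  cpset2 <- detect_change_points(sim$series)
  expect_identical(cpset$cps, cpset2$cps)
})

test_that("degenerate and unsuitable series are handled", {
  const <- make_series(rep(40, 500))
  expect_warning(cp <- detect_change_points(const), "degenerate")
  expect_equal(n_change_points(cp), 0)

  worn_off <- make_series(rep(40, 500),
                          code = c(rep("observed", 200), rep("absent", 300)))
  expect_error(detect_change_points(worn_off), "wear_fraction")
})

test_that("final per-regime models recover step inertia and flag f1 > 1", {
  regs <- list(regime_spec(0, 40 * 0.7, 0.3), regime_spec(3000, 40 * 0.2, 0.8))
  sim <- simulate_stress_series(regs, missing = missingness_spec(0, 0, 1, 0),
                                n_days = 12.5, noise_sd = 8, seed = 91)
  cpset <- detect_change_points(sim$series)
  expect_equal(n_change_points(cpset), 1)
  fin <- final_inertia_model(sim$series, cpset)
  expect_length(fin$models, 2)
  cv <- inertia_curve(fin)
  pairs <- build_lag_pairs(modeling_view(sim$series))
  for (i in 1:2) {
    rg <- cpset$regimes[i, ]
    sub <- pairs[pairs$t >= rg$start & pairs$t < rg$end, ]
    ols <- ols_ar1(sub)[2]                       # per-regime OLS oracle
    expect_lt(abs(mean(cv$f1[cv$regime_id == i]) - ols), 0.07)
    expect_lt(abs(mean(cv$f1[cv$regime_id == i]) - c(0.3, 0.8)[i]), 0.07)
  }
  expect_true(is.logical(cv$flag_gt1))

  # without change points the final model reduces to the gradual fit
  sim0 <- simulate_stress_series(regime_spec(0, 40 * 0.5, 0.5),
                                 missing = missingness_spec(0, 0, 1, 0),
                                 n_days = 25 / 6, noise_sd = 8, seed = 92)
  cp0 <- detect_change_points(sim0$series)
  expect_equal(n_change_points(cp0), 0)
  fin0 <- final_inertia_model(sim0$series, cp0)
  whole <- fit_tv_ar(build_lag_pairs(modeling_view(sim0$series)))
  expect_equal(inertia_curve(fin0)$f1, whole$ar_curve, tolerance = 1e-10)
})
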
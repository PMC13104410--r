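test_that("cumulative amount under full withdrawal is the running sampled sum", {
  ex <- franz_experiment(times = c(20, 40, 60), conc = cbind(c(1, 1, 1)),
                         C0_donor = 50, area = 1.77)
  expect_equal(as.numeric(cumulative_amount(ex)), c(2, 4, 6))
  ex0 <- franz_experiment(times = c(20, 40, 60), conc = cbind(c(0, 0, 0)),
                          C0_donor = 50, area = 1.77)
  expect_equal(as.numeric(cumulative_amount(ex0)), c(0, 0, 0))
})

test_that("cumulative amount matches the withdraw/replace event-simulation oracle", {
  times <- c(20, 40, 60, 80, 100, 120)
  for (rate in c(0.02, 0.11, 0.7)) {
    sim <- simulate_franz_events(rate, times, V_acceptor = 2)
    ex <- franz_experiment(times = times, conc = cbind(sim$conc),
                           C0_donor = 50, area = 1.77)
    expect_equal(as.numeric(cumulative_amount(ex)), sim$cumulative,
                 tolerance = 1e-12)
  }
  # partial withdrawal: back-correction reproduces the simulated truth
  sim <- simulate_franz_events(0.25, times, V_acceptor = 2, V_withdraw = 0.5)
  exp_part <- franz_experiment(times = times, conc = cbind(sim$conc),
                               C0_donor = 50, area = 1.77,
                               withdrawal = "partial", V_withdraw = 0.5)
  expect_equal(as.numeric(cumulative_amount(exp_part)), sim$cumulative,
               tolerance = 1e-12)
  expect_error(franz_experiment(times = times, conc = cbind(sim$conc),
                                C0_donor = 50, area = 1.77,
                                withdrawal = "partial"),
               "V_withdraw")
  # non-decreasing for non-negative concentrations
  set.seed(6)
  cc <- matrix(runif(18), 6, 3)
  exr <- franz_experiment(times = times, conc = cc, C0_donor = 50, area = 1.77)
  expect_true(all(apply(cumulative_amount(exr), 2, function(q)
    all(diff(q) >= 0))))
})

test_that("steady-state flux fits the line and converts units", {
  f <- steady_state_flux(c(2, 4, 6), c(20, 40, 60))
  expect_equal(f$slope_ug_min, 0.1)
  expect_equal(f$flux_ug_s, 0.1 / 60)
  expect_equal(steady_state_flux(c(3, 3, 3, 3), c(10, 20, 30, 40))$flux_ug_s, 0)
  expect_error(steady_state_flux(c(1, 2), c(10, 20)), "at least 3")
  expect_error(steady_state_flux(c(1, 2, 3), c(5, 5, 5)), "zero time span")
  # post-lag window drops the lag phase and recovers the true slope
  ex_lag <- gen_franz_series(1.25e-5, C0 = 50, lag_min = 20, seed = 3)
  Q <- cumulative_amount(ex_lag)[, 1]
  expect_lt(abs(Q[1]), 1e-9)  # first sample still inside the lag
  f_lag <- steady_state_flux(Q, ex_lag$times, window = "post-lag")
  papp <- apparent_permeability(f_lag$flux_ug_s, ex_lag$area, 50)
  expect_equal(papp, 1.25e-5, tolerance = 1e-9)
})

test_that("Papp normalises flux by area and donor concentration", {
  expect_equal(apparent_permeability(1 / 60, 2, 50), 1.667e-4,
               tolerance = 1e-3)
  expect_equal(apparent_permeability(0, 2, 50), 0)
  expect_error(apparent_permeability(1, 0, 50), "area")
  expect_error(apparent_permeability(1, 2, 0), "donor concentration")
})

test_that("noiseless simulator round-trips the true Papp to machine precision", {
  for (papp in c(3e-6, 1.25e-5, 4.7e-5)) {
    ex <- gen_franz_series(papp, C0 = 50, noise_cv = 0, seed = 1)
    res <- analyze_franz(ex)
    expect_lt(abs(res$papp_mean - papp) / papp, 1e-10)
    expect_equal(res$papp_sd, 0)
    # analytic sink model: % transport = 100 * Papp * A * C0 * t / dose
    expected_pct <- 100 * papp * 1.77 * 50 * 120 * 60 / (50 * 1)
    expect_equal(res$percent_mean, expected_pct, tolerance = 1e-10)
  }
})

test_that("unit coherence: refitting in hours gives the same Papp in cm/s", {
  ex <- gen_franz_series(1.25e-5, C0 = 50, noise_cv = 0.05, seed = 9)
  Q <- cumulative_amount(ex)[, 1]
  f_min <- steady_state_flux(Q, ex$times)
  fit_h <- stats::lm(Q ~ I(ex$times / 60))
  flux_h <- unname(coef(fit_h)[2]) / 3600
  expect_equal(f_min$flux_ug_s, flux_h, tolerance = 1e-12)
})

test_that("with 5% CV noise and 6 cells the mean Papp estimate stays within 10%", {
  for (papp in c(3e-6, 1.25e-5, 4.7e-5)) {
    means <- vapply(1:200, function(s)
      analyze_franz(gen_franz_series(papp, C0 = 50, noise_cv = 0.05,
                                     n_replicates = 6, seed = s))$papp_mean,
      0)
    expect_lt(abs(mean(means) - papp) / papp, 0.10)
  }
})

test_that("dose accounting: transport and tissue percentages, mass closure", {
  expect_equal(percent_transport(25, 50), 50)
  expect_equal(percent_transport(0, 50), 0)
  expect_error(percent_transport(25, 0), "dose")
  expect_equal(tissue_content_percent(0.5, dose = 50), 1)
  expect_equal(tissue_content_percent(lysate_conc = 0.1, dose = 50,
                                      lysate_volume = 5), 1)
  expect_error(tissue_content_percent(1, dose = -1), "dose")
  # conservation: donor remainder + acceptor recovery + tissue = dose
  dose <- 50
  ex <- gen_franz_series(1.25e-5, C0 = 50, noise_cv = 0, seed = 2)
  Q_final <- cumulative_amount(ex)[length(ex$times), 1]
  tissue <- 0.8
  donor_left <- dose - Q_final - tissue
  recovery <- percent_transport(Q_final, dose) +
    tissue_content_percent(tissue, dose = dose) +
    100 * donor_left / dose
  expect_equal(recovery, 100, tolerance = 1e-10)
  expect_lte(percent_transport(Q_final, dose), 100)
})

test_that("extract content percentages give the printed component donor doses", {
  expect_equal(donor_concentration_from_extract(20, 3.465), 693)
  expect_equal(donor_concentration_from_extract(20, 20.690), 4138)
  expect_equal(donor_concentration_from_extract(5, 100), 5000)  # x of 100%
  expect_error(donor_concentration_from_extract(20, 101), "exceed 100")
})

test_that("integrity gate uses a closed threshold; classification is nearest-benchmark", {
  expect_equal(integrity_check(2.92e-6, 5e-6), "pass")
  expect_equal(integrity_check(1e-4, 5e-6), "fail")
  expect_equal(integrity_check(5e-6, 5e-6), "pass")  # boundary passes
  expect_equal(classify_permeability(1.20e-5)$class, "low-moderate")
  expect_equal(classify_permeability(1e-7)$class, "low")
  expect_equal(classify_permeability(9e-5)$class, "moderate-high")
  expect_error(classify_permeability(1e-6, benchmarks = c(3, 2, 1)),
               "increasing")
})

test_that("long-format series files read back into a Franz experiment", {
  ex <- gen_franz_series(8.5e-6, C0 = 693, noise_cv = 0.05,
                         n_replicates = 3, seed = 12)
  df <- data.frame(replicate = rep(1:3, each = length(ex$times)),
                   time_min = rep(ex$times, 3),
                   conc_ug_per_ml = as.numeric(ex$conc))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  back <- read_franz_series(path, C0_donor = 693, area = 1.77)
  expect_equal(back$conc, ex$conc, ignore_attr = TRUE)
  expect_equal(back$times, ex$times)
  expect_equal(analyze_franz(back)$papp_mean, analyze_franz(ex)$papp_mean)
})
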
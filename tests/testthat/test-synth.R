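# Synthetic-data generators: determinism, noiseless closed forms, and the
# structural guarantees the downstream analyses rely on.

test_that("every generator is seed-deterministic", {
  a <- gen_tht_plate(tht_truth(), n_wells = 6, seed = 11)
  b <- gen_tht_plate(tht_truth(), n_wells = 6, seed = 11)
  expect_identical(a, b)

  expect_identical(gen_frap_series(frap_truth(), seed = 12),
                   gen_frap_series(frap_truth(), seed = 12))
  expect_identical(gen_photon_pair(tccd_truth(), seed = 13),
                   gen_photon_pair(tccd_truth(), seed = 13))
  expect_identical(gen_turbidity_series(seed = 14),
                   gen_turbidity_series(seed = 14))
  # different seed, different data
  expect_false(identical(gen_turbidity_series(seed = 14),
                         gen_turbidity_series(seed = 15)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(gen_tht_plate(tht_truth(), n_wells = 2, seed = 1))
  expect_identical(runif(1), before)
})

test_that("noiseless ThT wells agree with the closed-form sigmoid", {
  truth <- tht_truth(Fi = 100, Ff = 1100, t50_s = 3600, k_s = 400,
                     lag_cv = 0, noise_sd = 0)
  sim <- gen_tht_plate(truth, n_wells = 1, duration_s = 63000,
                       cycle_s = 350, seed = 5)
  tr <- sim$plate$traces[[1]]
  expect_equal(tr$intensity,
               boltzmann_closed_form(tr$time_s, 100, 1100, 3600, 400),
               tolerance = 1e-12)
  expect_equal(sim$truth$t_lag_tangent_s, 3600 - 800)
  expect_equal(sim$truth$t_lag_paper_s, 4 * 400 * 100 / 1000 + 3600 - 800)
})

test_that("non-aggregating wells are flat and recorded as such", {
  sim <- gen_tht_plate(tht_truth(nonaggregating_frac = 1, noise_sd = 0),
                       n_wells = 8, seed = 21)
  expect_true(all(!sim$truth$aggregating))
  for (tr in sim$plate$traces)
    expect_equal(sd(tr$intensity), 0)
})

test_that("per-well midpoints follow the requested lognormal scatter", {
  truth <- tht_truth(lag_cv = 0.25, noise_sd = 0)
  sim <- gen_tht_plate(truth, n_wells = 400, seed = 31)
  t50 <- sim$truth$t50_s
  expect_equal(mean(t50), 3600, tolerance = 0.05)
  expect_equal(sd(t50) / mean(t50), 0.25, tolerance = 0.15)
  expect_true(all(t50 > 0))
})

test_that("noiseless FRAP series has exact limits and paper-like framing", {
  # immobile: post-bleach roi constant at the bleached level
  ser0 <- gen_frap_series(frap_truth(mobile_fraction = 0, noise_sd = 0,
                                     bleach_depth = 0.8),
                          n_pre = 5, n_post = 30, seed = 1, acq_decay = 0)
  post <- ser0$roi[ser0$bleach_index:length(ser0$roi)]
  expect_equal(sd(post), 0)

  # fully mobile: recovery approaches the reference-scaled pre-bleach level
  ser1 <- gen_frap_series(frap_truth(mobile_fraction = 1, noise_sd = 0,
                                     t_half_s = 1),
                          n_pre = 5, n_post = 200, dt_s = 0.5, seed = 1,
                          acq_decay = 0)
  pre_ratio <- (ser1$roi[1] - ser1$background[1]) /
    (ser1$reference[1] - ser1$background[1])
  n <- length(ser1$roi)
  end_ratio <- (ser1$roi[n] - ser1$background[n]) /
    (ser1$reference[n] - ser1$background[n])
  expect_equal(end_ratio, pre_ratio, tolerance = 1e-9)

  # default sampling matches a ~90 s acquisition at ~0.171 s intervals
  ser <- gen_frap_series(frap_truth(), seed = 2)
  expect_equal(length(ser$time_s) - (ser$bleach_index - 1L), 526)
})

test_that("photon pair construction honors the coincidence bookkeeping", {
  # all coincident, zero jitter: identical truth times in both channels
  pp <- gen_photon_pair(tccd_truth(coincident_fraction = 1,
                                   n_bursts_per_channel = 50,
                                   duration_s = 20),
                        seed = 41, jitter_ms = 0)
  expect_identical(pp$truth$times_a_ms, pp$truth$times_b_ms)

  # half coincident: the shared list has exactly half the bursts
  pp2 <- gen_photon_pair(tccd_truth(coincident_fraction = 0.5,
                                    n_bursts_per_channel = 100,
                                    duration_s = 30), seed = 42)
  expect_length(pp2$truth$coincident_a_ms, 50)
  expect_length(pp2$truth$times_a_ms, 100)
  expect_length(pp2$truth$times_b_ms, 100)
  expect_true(all(abs(pp2$truth$coincident_b_ms -
                        pp2$truth$coincident_a_ms) <= 2))

  # burst-free trace is pure background
  pp3 <- gen_photon_pair(tccd_truth(n_bursts_per_channel = 0), seed = 43)
  expect_lt(max(pp3$a$counts), 10 + 6 * 2)

  # within-channel minimum spacing
  expect_gte(min(diff(pp2$truth$times_a_ms)), 3 * 2)

  # dilute-regime occupancy guard
  expect_error(gen_photon_pair(tccd_truth(n_bursts_per_channel = 2000,
                                          burst_width_ms = 2,
                                          duration_s = 10), seed = 1),
               "occupancy", class = "aggkinetics_validation_error")
})

test_that("turbidity series saturates to od_max and samples the full grid", {
  ts0 <- gen_turbidity_series(od_max = 0, noise_sd = 0.001, seed = 51)
  expect_lt(abs(mean(ts0$od[["600"]])), 0.001)

  ts1 <- gen_turbidity_series(od_max = 0.5, rate_per_s = 0.5, noise_sd = 0,
                              duration_s = 300, dt_s = 10, seed = 52)
  expect_length(ts1$time_s, 30)
  expect_equal(tail(ts1$od[["340"]], 1), 0.5, tolerance = 1e-9)
  expect_equal(tail(ts1$od[["340"]], 1) /
                 (1 - exp(-0.5 * ts1$time_s[30])), 0.5, tolerance = 1e-12)
})
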
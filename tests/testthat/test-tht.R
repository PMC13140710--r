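# Boltzmann fitting and the kinetic summaries derived from it.

test_that("noiseless synthetic traces are recovered to 1e-6 relative", {
  truth <- tht_truth(Fi = 100, Ff = 1100, t50_s = 3600, k_s = 400,
                     lag_cv = 0, noise_sd = 0)
  sim <- gen_tht_plate(truth, n_wells = 1, duration_s = 63000,
                       cycle_s = 350, seed = 1)
  fit <- fit_boltzmann(sim$plate$traces[[1]])
  expect_true(fit$converged)
  expect_equal(fit$Fi, 100, tolerance = 1e-6)
  expect_equal(fit$Ff, 1100, tolerance = 1e-6)
  expect_equal(fit$t50_s, 3600, tolerance = 1e-6)
  expect_equal(fit$k_s, 400, tolerance = 1e-6)
  expect_gt(fit$r2, 1 - 1e-9)
})

test_that("kinetic summaries evaluate the printed formulas", {
  tr <- flat_trace()  # endpoint source only
  s1 <- kinetic_summary(make_fit(0, 400, 1000, 10), tr)
  expect_equal(s1$elongation_rate, 10)
  expect_equal(s1$t_lag_paper_s, 980)
  expect_equal(s1$t_lag_tangent_s, 980)

  s2 <- kinetic_summary(make_fit(100, 1100, 3600, 400), tr)
  expect_equal(s2$elongation_rate, 0.625)
  expect_equal(s2$t_lag_tangent_s, 2800)
  expect_equal(s2$t_lag_paper_s, 2960)
  expect_equal(s2$delta_I, 1000)
  expect_equal(s2$endpoint, 100)  # mean of the final three raw points

  expect_error(kinetic_summary(make_fit(500, 500, 1000, 10), tr),
               "division", class = "aggkinetics_validation_error")
})

test_that("elongation rate equals the slope of the fitted curve at t50", {
  set.seed(77)
  for (i in 1:25) {
    Fi <- runif(1, 0, 200); Ff <- Fi + runif(1, 100, 2000)
    t50 <- runif(1, 1000, 10000); k <- runif(1, 50, 1000)
    rate <- kinetic_summary(make_fit(Fi, Ff, t50, k), flat_trace())$elongation_rate
    h <- 1e-3 * k
    num <- (boltzmann_closed_form(t50 + h, Fi, Ff, t50, k) -
              boltzmann_closed_form(t50 - h, Fi, Ff, t50, k)) / (2 * h)
    expect_equal(rate, num, tolerance = 1e-6)
  }
})

test_that("flat traces are reported as transition-free, not fitted", {
  fit <- fit_boltzmann(flat_trace(level = 100))
  expect_false(fit$converged)
  expect_match(fit$reason, "no transition")
  # flat plus noise: no convincing sigmoid either
  set.seed(8)
  tr <- tht_trace("A1", 350 * (0:179), rnorm(180, 100, 5))
  fit2 <- fit_boltzmann(tr)
  expect_false(fit2$converged)
})

test_that("percent protection follows the amplitude-difference formula", {
  expect_identical(percent_protection(1000, 0), 100)
  expect_identical(percent_protection(1000, 1000), 0)
  expect_identical(percent_protection(1000, 1500), -50)
  expect_error(percent_protection(0, 10), class = "aggkinetics_validation_error")

  # antitone in the chaperone amplitude, and the exact algebraic identity
  set.seed(17)
  ref <- runif(1, 500, 2000)
  chap <- sort(runif(20, 0, 3000))
  prot <- vapply(chap, function(ci) percent_protection(ref, ci), numeric(1))
  expect_true(all(diff(prot) < 0))
  expect_equal(prot, 100 - 100 * chap / ref, tolerance = 1e-12)
})

test_that("event coding classifies wells and censors the quiet ones", {
  # flat noise: censored at assay end
  set.seed(23)
  tr <- tht_trace("A1", 350 * (0:179), rnorm(180, 100, 5))
  ev <- detect_event(tr)
  expect_identical(ev$event, 0L)
  expect_identical(ev$time_s, max(tr$time_s))

  # strongly aggregating well on the long-assay timescale: event stamped
  # within 5% of the true lag
  truth <- tht_truth(Fi = 100, Ff = 1100, t50_s = 36000, k_s = 2000,
                     lag_cv = 0.2, noise_sd = 2)  # amplitude 500x baseline sd
  sim <- gen_tht_plate(truth, n_wells = 12, duration_s = 742 * 350,
                       cycle_s = 350, seed = 24)
  res <- analyze_plate(sim$plate)
  expect_true(all(res$event == 1L))
  rel_err <- abs(res$time_s - sim$truth$t_lag_paper_s) /
    sim$truth$t_lag_paper_s
  expect_lt(max(rel_err), 0.05)
})

test_that("censored fraction of a mixed plate matches the generator", {
  truth <- tht_truth(Fi = 100, Ff = 1100, t50_s = 36000, k_s = 2000,
                     lag_cv = 0.2, nonaggregating_frac = 0.3, noise_sd = 20)
  sim <- gen_tht_plate(truth, n_wells = 100, duration_s = 742 * 350,
                       cycle_s = 350, seed = 25)
  res <- analyze_plate(sim$plate)
  censored <- sum(res$event == 0L)
  # binomial 99% interval around 30/100
  expect_gte(censored, qbinom(0.005, 100, 0.3))
  expect_lte(censored, qbinom(0.995, 100, 0.3))
  # and the detector agrees with the generator's event labels well-by-well
  expect_identical(res$event == 1L, sim$truth$aggregating)
})

test_that("protection table ranks chaperone doses against the reference", {
  mk <- function(cond, Ff, n = 4, frac = 0) {
    truth <- tht_truth(Fi = 100, Ff = Ff, t50_s = 36000, k_s = 2000,
                       lag_cv = 0.1, nonaggregating_frac = frac,
                       noise_sd = 5)
    sim <- gen_tht_plate(truth, n_wells = n, duration_s = 742 * 350,
                         seed = nchar(cond) + Ff)
    res <- analyze_plate(sim$plate)
    res$condition <- cond
    res
  }
  res <- rbind(mk("alone", 1100), mk("chap 1:1", 350),
               mk("chap 5:1", 150, frac = 1))
  tab <- protection_table(res, reference = "alone")
  prot <- setNames(tab$percent_protection, tab$condition)
  expect_equal(prot[["alone"]], 0, tolerance = 1e-9)
  expect_gt(prot[["chap 1:1"]], 60)
  expect_gt(prot[["chap 5:1"]], 95)
  expect_true(prot[["chap 5:1"]] > prot[["chap 1:1"]])
})
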
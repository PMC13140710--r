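# Scalar quantifications: extinction coefficients, degree of labeling,
# dilute-phase fraction, delta-OD.

test_that("extinction coefficients follow the composition rule", {
  expect_identical(extinction_coefficient("Y"), 1490L)
  expect_identical(extinction_coefficient("WWYC"), 12490L)
  expect_identical(extinction_coefficient("WWYC", "oxidized"), 12615L)
  expect_identical(extinction_coefficient("GSGSGS"), 0L)
  # case and whitespace insensitive
  expect_identical(extinction_coefficient("w y\n c", "oxidized"),
                   5500L + 1490L + 125L)
  expect_error(extinction_coefficient("ACDX"), "position 4",
               class = "aggkinetics_validation_error")
  expect_error(extinction_coefficient(""), class = "aggkinetics_validation_error")
})

test_that("reduced-mode coefficients are additive over concatenation", {
  set.seed(81)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:20) {
    s1 <- paste(sample(aa, 30, replace = TRUE), collapse = "")
    s2 <- paste(sample(aa, 40, replace = TRUE), collapse = "")
    expect_identical(extinction_coefficient(paste0(s1, s2)),
                     extinction_coefficient(s1) + extinction_coefficient(s2))
  }
})

test_that("bundled construct sequences give the assay's working coefficients", {
  # tagged expression construct of the TDP-43 low-complexity domain: the
  # TEV-site tyrosine in the leader adds 1490 over the bare region
  expect_identical(
    extinction_coefficient(construct_fasta("tdp43_lcd_construct")), 19480L)
  expect_identical(extinction_coefficient(construct_fasta("tdp43_lcd")),
                   17990L)
  expect_identical(
    extinction_coefficient(construct_fasta("hspb1_acd"), "oxidized"), 8605L)
  expect_identical(extinction_coefficient(construct_fasta("hspb5_acd")),
                   1490L)
})

test_that("degree of labeling is the corrected molar dye:protein ratio", {
  # equimolar: a280 corrected to 0.2 -> 10 uM protein; dye 0.5/50000 -> 10 uM
  expect_equal(degree_of_labeling(a280 = 0.2 + 0.08 * 0.5, a_dye = 0.5,
                                  eps_protein = 20000, eps_dye = 50000),
               100, tolerance = 1e-12)
  expect_equal(degree_of_labeling(0.3, 0, 20000, 50000), 0)
  expect_error(degree_of_labeling(0.1, 1.25, 20000, 50000),
               class = "aggkinetics_validation_error")

  # invariant to rescaling both absorbances by a common gain
  set.seed(82)
  for (i in 1:10) {
    a280 <- runif(1, 0.2, 1); adye <- runif(1, 0, 1); g <- runif(1, 0.1, 10)
    expect_equal(degree_of_labeling(g * a280, g * adye, 19480, 271000),
                 degree_of_labeling(a280, adye, 19480, 271000),
                 tolerance = 1e-12)
  }
})

test_that("dilute-phase fraction applies Beer-Lambert and flags overshoot", {
  expect_equal(dilute_phase_fraction(0, 19480, 20)$dilute_fraction, 0)

  # absorbance chosen so the dilute concentration equals the input
  a <- 19480 * 0.1 * 20e-6
  q <- dilute_phase_fraction(a, 19480, 20, path_cm = 0.1)
  expect_equal(q$dilute_fraction, 1, tolerance = 1e-12)
  expect_false(q$flagged)
  expect_true(dilute_phase_fraction(2 * a, 19480, 20)$flagged)
  expect_error(dilute_phase_fraction(-0.1, 19480, 20),
               class = "aggkinetics_validation_error")

  # a titration that drives more protein into condensates must give a
  # monotonically decreasing dilute fraction
  salt <- seq(0, 500, by = 100)
  a_sup <- 19480 * 0.1 * 20e-6 * exp(-salt / 250)
  fr <- vapply(a_sup, function(ai)
    dilute_phase_fraction(ai, 19480, 20)$dilute_fraction, numeric(1))
  expect_true(all(diff(fr) < 0))
})

test_that("delta-OD is an endpoint difference with a robust default", {
  flat <- turbidity_series("A1", 1:10, data.frame(`600` = rep(0.2, 10),
                                                  check.names = FALSE))
  expect_equal(delta_od(flat, "600"), 0)

  rise <- turbidity_series("A1", 1:10,
                           data.frame(`600` = c(rep(0, 5), rep(0.3, 5)),
                                      check.names = FALSE))
  expect_equal(delta_od(rise, "600"), 0.3)
  expect_equal(delta_od(rise, "600", literal_endpoint = TRUE), 0.3)
  # antisymmetry under time reversal
  fall <- turbidity_series("A1", 1:10,
                           data.frame(`600` = rev(c(rep(0, 5), rep(0.3, 5))),
                                      check.names = FALSE))
  expect_equal(delta_od(fall, "600"), -delta_od(rise, "600"))

  expect_error(delta_od(rise, "340"), "340",
               class = "aggkinetics_validation_error")

  # saturating synthetic curve, duration >> 1/rate: delta-OD ~ od_max
  ts <- gen_turbidity_series(od_max = 0.5, rate_per_s = 5e-4,
                             noise_sd = 0.005, duration_s = 1e4,
                             dt_s = 10, seed = 83)
  expect_equal(delta_od(ts, "340"), 0.5, tolerance = 0.02)
})
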
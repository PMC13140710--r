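# Two-color coincidence detection: noise model, peak finding, matching.

test_that("noise-model identities are exact and the fit recovers a Gaussian", {
  # formula identities on a synthetic model with sigma = 1
  nm <- structure(list(p_center = 10, sigma = 1,
                       fwhm = 2 * sqrt(2 * log(2)) * 1,
                       threshold = 10 + 2 * 2 * sqrt(2 * log(2))),
                  class = "noise_model")
  expect_equal(nm$fwhm, 2.3548, tolerance = 1e-4)
  expect_equal(nm$threshold - nm$p_center, 4.7096, tolerance = 1e-4)

  # fitted model on a burst-free normal trace
  set.seed(71)
  tr <- photon_trace(round(pmax(0, rnorm(1e5, 10, 2))), 1)
  fit <- fit_noise(tr)
  expect_equal(fit$p_center, 10, tolerance = 0.02)
  expect_equal(fit$fwhm, 2 * sqrt(2 * log(2)) * 2, tolerance = 0.02)
  expect_equal(fit$threshold, fit$p_center + 2 * fit$fwhm, tolerance = 1e-12)
  expect_equal(fit$fwhm / fit$sigma, 2.354820045, tolerance = 1e-9)

  expect_error(fit_noise(photon_trace(rep(5, 500), 1)), "degenerate",
               class = "aggkinetics_validation_error")
})

test_that("rare bright bursts barely move the fitted threshold", {
  set.seed(72)
  base <- round(pmax(0, rnorm(2e4, 10, 2)))
  thr0 <- fit_noise(photon_trace(base, 1))$threshold
  spiked <- base
  idx <- sample(length(base), length(base) %/% 100)  # 1% burst bins
  spiked[idx] <- spiked[idx] + 40                    # 20 sigma
  thr1 <- fit_noise(photon_trace(spiked, 1))$threshold
  expect_lt(abs(thr1 - thr0) / thr0, 0.05)
})

test_that("peak finding enforces threshold and minimum separation", {
  counts <- rep(5L, 1000)
  nm <- list(threshold = 20)

  # two spikes 20 ms apart at 1 ms bins: only the taller survives at 40 ms
  counts2 <- counts
  counts2[c(100, 120)] <- c(50L, 60L)
  pk <- find_peaks(photon_trace(counts2, 1), nm, min_separation_ms = 40)
  expect_length(pk$times_ms, 1)
  expect_equal(pk$heights, 60)
  expect_equal(pk$times_ms, 119.5)

  # 60 ms apart: both kept, times strictly increasing
  counts3 <- counts
  counts3[c(100, 160)] <- c(50L, 60L)
  pk3 <- find_peaks(photon_trace(counts3, 1), nm, min_separation_ms = 40)
  expect_length(pk3$times_ms, 2)
  expect_true(all(diff(pk3$times_ms) > 0))

  # sub-threshold bumps are ignored; empty sets allowed
  counts4 <- counts
  counts4[300] <- 15L
  expect_length(find_peaks(photon_trace(counts4, 1), nm)$times_ms, 0)
})

test_that("well-separated bright bursts are essentially all detected", {
  pp <- gen_photon_pair(tccd_truth(n_bursts_per_channel = 500,
                                   coincident_fraction = 0,
                                   burst_amplitude = 20,  # 10 sigma
                                   duration_s = 60), seed = 73)
  pk <- find_peaks(pp$a, fit_noise(pp$a))
  truth_times <- pp$truth$times_a_ms
  hit <- vapply(truth_times,
                function(t0) any(abs(pk$times_ms - t0) <= 5), logical(1))
  expect_gte(mean(hit), 0.99)
  # false positives bounded by the Gaussian tail beyond the threshold
  n_extra <- length(pk$times_ms) - sum(hit)
  n_bins <- length(pp$a$counts)
  p_tail <- pnorm(fit_noise(pp$a)$threshold, 10, 2, lower.tail = FALSE)
  expect_lte(n_extra, max(5, 3 * n_bins * p_tail))
})

test_that("coincidence matching is windowed, symmetric and one-to-one", {
  mk_peaks <- function(times, channel = "a", duration = 10000)
    structure(list(times_ms = times, heights = rep(100, length(times)),
                   channel = channel, threshold = 20,
                   duration_ms = duration), class = "peak_set")

  # identical peak times: 100%
  pa <- mk_peaks(c(100, 500, 900))
  expect_equal(coincidence(pa, mk_peaks(c(100, 500, 900), "b"))
               $percent_coincident_ref, 100)

  # all offsets beyond the window: 0 pairs
  off <- mk_peaks(c(115, 515, 915), "b")
  expect_equal(coincidence(pa, off, window_ms = 10)$n_coincident, 0)

  # swap symmetry of the pair set
  pb <- mk_peaks(c(96, 504, 2000), "b")
  ab <- coincidence(pa, pb)
  ba <- coincidence(pb, pa)
  expect_equal(ab$coincident_pairs[, "time_a_ms"],
               ba$coincident_pairs[, "time_b_ms"])
  expect_equal(ab$n_coincident, ba$n_coincident)

  # empty reference channel: undefined, not zero
  none <- mk_peaks(numeric(0))
  res <- coincidence(none, pb, reference = "a")
  expect_false(res$defined)
  expect_true(is.na(res$percent_coincident_ref))
})

test_that("greedy matching is optimal when pairs do not compete, never double-counts", {
  set.seed(74)
  mk_peaks <- function(times, channel)
    structure(list(times_ms = sort(times), heights = rep(100, length(times)),
                   channel = channel, threshold = 20, duration_ms = 1e5),
              class = "peak_set")
  for (rep in 1:40) {
    na <- sample(0:10, 1); nb <- sample(0:10, 1)
    ta <- sort(runif(na, 0, 2000))
    tb <- sort(runif(nb, 0, 2000))
    res <- coincidence(mk_peaks(ta, "a"), mk_peaks(tb, "b"), window_ms = 25)
    # one-to-one: no peak reused
    expect_false(any(duplicated(res$coincident_pairs[, 1])))
    expect_false(any(duplicated(res$coincident_pairs[, 2])))
    expect_lte(res$n_coincident, min(na, nb))
    best <- max_matching_oracle(ta, tb, 25)
    expect_lte(res$n_coincident, best)
    # non-competing candidates (each peak has at most one partner):
    # greedy attains the maximum matching
    n_partners_a <- rowSums(abs(outer(ta, tb, `-`)) <= 25)
    n_partners_b <- colSums(abs(outer(ta, tb, `-`)) <= 25)
    if (all(n_partners_a <= 1) && all(n_partners_b <= 1))
      expect_identical(res$n_coincident, as.integer(best))
  }
})

test_that("coincident-fraction estimates tighten as 1/sqrt(n)", {
  errs <- vapply(c(100, 400, 1600), function(n) {
    pp <- gen_photon_pair(tccd_truth(n_bursts_per_channel = n,
                                     coincident_fraction = 0.5,
                                     duration_s = max(10, n / 10)),
                          seed = 75)
    pa <- find_peaks(pp$a, fit_noise(pp$a))
    pb <- find_peaks(pp$b, fit_noise(pp$b))
    abs(coincidence(pa, pb)$percent_coincident_ref - 50)
  }, numeric(1))
  # against binomial scaling: error should stay within ~3 SE at each n
  se <- 100 * sqrt(0.25 / c(100, 400, 1600))
  expect_true(all(errs <= 3 * se))
})

test_that("chance-coincidence diagnostic is small for sparse traces", {
  pp <- gen_photon_pair(tccd_truth(n_bursts_per_channel = 50,
                                   coincident_fraction = 1,
                                   duration_s = 30), seed = 76)
  pa <- find_peaks(pp$a, fit_noise(pp$a))
  pb <- find_peaks(pp$b, fit_noise(pp$b))
  measured <- coincidence(pa, pb)$percent_coincident_ref
  chance <- chance_coincidence(pa, pb, n_mc = 50, seed = 7)
  expect_gt(measured, 95)
  expect_lt(chance, 25)
})
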
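# synth module: seed-deterministic generators with known ground truth for
# every downstream analysis stage.

# ---- truth parameter objects -----------------------------------------------

#' Ground-truth parameters for a synthetic ThT plate
#'
#' Defaults describe an agitated amyloid fibrillation assay read on a
#' 350-second plate-reader cycle: a sigmoidal transition of roughly tenfold
#' amplitude over the baseline, a midpoint an hour into the assay, 2%
#' amplitude measurement noise and 20% well-to-well scatter of the nucleation
#' midpoint.
#'
#' @param Fi Baseline fluorescence, arbitrary units (a.u.).
#' @param Ff Plateau fluorescence, a.u.; must exceed `Fi`.
#' @param t50_s Population midpoint (time to half-maximal fluorescence), s.
#' @param k_s Sigmoid slope parameter, s; larger is shallower.
#' @param lag_cv Coefficient of variation of the per-well midpoint. Per-well
#'   midpoints are drawn lognormally (nucleation times are strictly positive
#'   and right-skewed) with mean `t50_s` and this CV.
#' @param nonaggregating_frac Probability that a well never aggregates and
#'   stays at baseline (right-censored downstream).
#' @param noise_sd Gaussian measurement noise, a.u.
#' @return An object of class `tht_truth`.
#' @export
tht_truth <- function(Fi = 100, Ff = 1100, t50_s = 3600, k_s = 400,
                      lag_cv = 0.2, nonaggregating_frac = 0, noise_sd = 20) {
  assert_scalar_number(Fi, "Fi", lower = 0)
  assert_scalar_number(Ff, "Ff")
  if (Ff <= Fi) stop_validation("Ff must exceed Fi")
  assert_scalar_number(k_s, "k_s")
  if (k_s <= 0) stop_validation("k_s must be positive")
  assert_scalar_number(lag_cv, "lag_cv", lower = 0)
  assert_scalar_number(nonaggregating_frac, "nonaggregating_frac", 0, 1)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  structure(list(Fi = Fi, Ff = Ff, t50_s = t50_s, k_s = k_s, lag_cv = lag_cv,
                 nonaggregating_frac = nonaggregating_frac,
                 noise_sd = noise_sd),
            class = "tht_truth")
}

#' Ground-truth parameters for a synthetic FRAP series
#'
#' Defaults describe a liquid-like condensate bleached to 20% of its
#' pre-bleach signal that recovers 60% of the bleached amplitude with a
#' five-second half-time, with 2% relative measurement noise.
#'
#' @param mobile_fraction Fraction of the bleached amplitude that recovers,
#'   in `[0, 1]`.
#' @param t_half_s Half-time of recovery, seconds, positive.
#' @param bleach_depth Fraction of the pre-bleach signal removed by the
#'   bleach pulse, in `(0, 1]`.
#' @param noise_sd Gaussian noise relative to the pre-bleach signal.
#' @return An object of class `frap_truth`.
#' @export
frap_truth <- function(mobile_fraction = 0.6, t_half_s = 5,
                       bleach_depth = 0.8, noise_sd = 0.02) {
  assert_scalar_number(mobile_fraction, "mobile_fraction", 0, 1)
  assert_scalar_number(t_half_s, "t_half_s")
  if (t_half_s <= 0) stop_validation("t_half_s must be positive")
  assert_scalar_number(bleach_depth, "bleach_depth", 0, 1)
  if (bleach_depth == 0) stop_validation("bleach_depth must be positive")
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  structure(list(mobile_fraction = mobile_fraction, t_half_s = t_half_s,
                 bleach_depth = bleach_depth, noise_sd = noise_sd),
            class = "frap_truth")
}

#' Ground-truth parameters for a synthetic two-channel photon trace pair
#'
#' Defaults describe a dilute single-molecule acquisition: order-100 bursts
#' over tens of seconds, Gaussian-profile bursts two milliseconds wide and
#' twenty standard deviations above a shot-noise-like background, with half
#' the bursts shared between the two channels.
#'
#' @param n_bursts_per_channel Bursts per channel (coincident bursts count in
#'   both channels).
#' @param coincident_fraction Fraction of bursts sharing a center time across
#'   channels, in `[0, 1]`.
#' @param burst_amplitude Peak burst height above background, counts.
#' @param burst_width_ms Burst full width at half maximum, ms.
#' @param bg_mean Background mean, counts per bin.
#' @param bg_sd Background standard deviation, counts per bin.
#' @param duration_s Trace duration, seconds.
#' @return An object of class `tccd_truth`.
#' @export
tccd_truth <- function(n_bursts_per_channel = 100, coincident_fraction = 0.5,
                       burst_amplitude = 40, burst_width_ms = 2,
                       bg_mean = 10, bg_sd = 2, duration_s = 10) {
  assert_scalar_number(n_bursts_per_channel, "n_bursts_per_channel", lower = 0)
  assert_scalar_number(coincident_fraction, "coincident_fraction", 0, 1)
  assert_scalar_number(burst_amplitude, "burst_amplitude")
  if (burst_amplitude <= 0) stop_validation("burst_amplitude must be positive")
  assert_scalar_number(burst_width_ms, "burst_width_ms")
  if (burst_width_ms <= 0) stop_validation("burst_width_ms must be positive")
  assert_scalar_number(bg_mean, "bg_mean", lower = 0)
  assert_scalar_number(bg_sd, "bg_sd", lower = 0)
  assert_scalar_number(duration_s, "duration_s")
  structure(list(n_bursts_per_channel = as.integer(n_bursts_per_channel),
                 coincident_fraction = coincident_fraction,
                 burst_amplitude = burst_amplitude,
                 burst_width_ms = burst_width_ms, bg_mean = bg_mean,
                 bg_sd = bg_sd, duration_s = duration_s),
            class = "tccd_truth")
}

# ---- ThT plate --------------------------------------------------------------

# closed-form sigmoid shared by the generator; the fitting routine states the
# model independently inside its nls formula
boltzmann_curve <- function(t, Fi, Ff, t50, k) {
  Fi + (Ff - Fi) / (1 + exp((t50 - t) / k))
}

well_ids <- function(n) {
  if (n <= 384) {
    rows <- LETTERS[1:16]
    ids <- as.vector(t(outer(rows, 1:24, paste0)))
    ids[seq_len(n)]
  } else sprintf("W%04d", seq_len(n))
}

#' Generate a synthetic ThT kinetic plate with known truth
#'
#' Aggregating wells follow a Boltzmann sigmoid whose midpoint is drawn
#' lognormally across wells (mean `t50_s`, CV `lag_cv`); non-aggregating
#' wells (chosen Bernoulli with `nonaggregating_frac`) stay flat at baseline.
#' Gaussian noise is added to every point. The returned truth table carries
#' each well's generating parameters and the implied lag times, so every
#' downstream estimand can be checked without re-derivation.
#'
#' @param truth A [tht_truth()] object.
#' @param n_wells Number of wells.
#' @param duration_s Assay duration in seconds (at least 10 cycles).
#' @param cycle_s Cycle time in seconds; readings at the start of each cycle.
#' @param seed Integer seed; identical seeds give identical plates.
#' @return A list with elements `plate` ([plate_kinetics()]) and `truth`
#'   (data frame: `well_id`, `aggregating`, `Fi`, `Ff`, `t50_s`, `k_s`,
#'   `t_lag_paper_s`, `t_lag_tangent_s`).
#' @export
gen_tht_plate <- function(truth = tht_truth(), n_wells = 96,
                          duration_s = 63000, cycle_s = 350, seed) {
  stopifnot(inherits(truth, "tht_truth"))
  if (n_wells < 1) stop_validation("n_wells must be at least 1")
  if (duration_s < 10 * cycle_s)
    stop_validation("duration_s must cover at least 10 cycles")
  with_seed(seed, {
    n_cycles <- floor(duration_s / cycle_s)
    time_s <- cycle_s * (0:(n_cycles - 1))
    ids <- well_ids(n_wells)
    aggregating <- runif(n_wells) >= truth$nonaggregating_frac
    sdlog <- sqrt(log(1 + truth$lag_cv^2))
    meanlog <- log(truth$t50_s) - sdlog^2 / 2  # mean of lognormal = t50_s
    t50_i <- rlnorm(n_wells, meanlog, sdlog)
    amp <- truth$Ff - truth$Fi
    traces <- vector("list", n_wells)
    for (i in seq_len(n_wells)) {
      mu <- if (aggregating[i])
        boltzmann_curve(time_s, truth$Fi, truth$Ff, t50_i[i], truth$k_s)
      else rep(truth$Fi, length(time_s))
      noise <- if (truth$noise_sd > 0)
        rnorm(length(time_s), 0, truth$noise_sd) else 0
      traces[[i]] <- tht_trace(ids[i], time_s, mu + noise)
    }
    truth_tab <- data.frame(
      well_id = ids, aggregating = aggregating,
      Fi = truth$Fi, Ff = ifelse(aggregating, truth$Ff, truth$Fi),
      t50_s = ifelse(aggregating, t50_i, NA_real_), k_s = truth$k_s,
      stringsAsFactors = FALSE)
    truth_tab$t_lag_paper_s <- ifelse(
      aggregating, 4 * truth$k_s * truth$Fi / amp + t50_i - 2 * truth$k_s,
      NA_real_)
    truth_tab$t_lag_tangent_s <- ifelse(aggregating, t50_i - 2 * truth$k_s,
                                        NA_real_)
    list(plate = plate_kinetics(traces, cycle_s = cycle_s,
                                meta = list(generator = "gen_tht_plate",
                                            seed = seed)),
         truth = truth_tab)
  })
}

# ---- FRAP -------------------------------------------------------------------

#' Generate a synthetic FRAP series with known truth
#'
#' The underlying condensate signal decays linearly by `acq_decay` over the
#' series (acquisition photobleaching, affecting bleached ROI and reference
#' alike, so reference normalization must remove it). At the bleach frame the
#' ROI drops instantaneously by `bleach_depth`, then recovers
#' `mobile_fraction * (1 - 2^(-t / t_half))` of the bleached amplitude. In
#' the noiseless limit, full-scale normalization of the output returns that
#' closed form exactly.
#'
#' @param truth A [frap_truth()] object.
#' @param n_pre Pre-bleach frames (at least 3).
#' @param n_post Post-bleach frames (at least 20). The default matches a
#'   90-second acquisition at 0.171-second intervals.
#' @param dt_s Frame interval, seconds.
#' @param seed Integer seed.
#' @param roi_scale Ratio of bleached-ROI to whole-condensate intensity.
#' @param base_intensity Pre-bleach condensate intensity, a.u.
#' @param background Constant background level, a.u.
#' @param acq_decay Total fractional linear decay of the condensate signal
#'   over the series from acquisition photobleaching.
#' @return A [frap_series()] object with the truth attached as attribute
#'   `"truth"`.
#' @export
gen_frap_series <- function(truth = frap_truth(), n_pre = 10,
                            n_post = round(90 / 0.171), dt_s = 0.171, seed,
                            roi_scale = 0.6, base_intensity = 1000,
                            background = 100, acq_decay = 0.05) {
  stopifnot(inherits(truth, "frap_truth"))
  if (n_pre < 3) stop_validation("n_pre must be at least 3")
  if (n_post < 20) stop_validation("n_post must be at least 20")
  with_seed(seed, {
    n <- n_pre + n_post
    time_s <- dt_s * (0:(n - 1))
    tau <- pmax(0, time_s - time_s[n_pre + 1])
    post <- seq_len(n) > n_pre
    recovery <- ifelse(
      post,
      (1 - truth$bleach_depth) +
        truth$bleach_depth * truth$mobile_fraction *
          (1 - 2^(-tau / truth$t_half_s)),
      1)
    cond <- base_intensity * (1 - acq_decay * time_s / max(time_s))
    nz <- function() if (truth$noise_sd > 0)
      rnorm(n, 0, truth$noise_sd * base_intensity) else 0
    out <- frap_series(time_s,
                       roi = roi_scale * cond * recovery + background + nz(),
                       reference = cond + background + nz(),
                       background = rep(background, n) + nz(),
                       bleach_index = n_pre + 1L)
    attr(out, "truth") <- truth
    out
  })
}

# ---- TCCD -------------------------------------------------------------------

#' Generate a synthetic two-channel photon trace pair with known truth
#'
#' Background counts per bin are Gaussian, truncated at zero and rounded.
#' Bursts have Gaussian time profiles (FWHM `burst_width_ms`) placed at
#' uniformly random times subject to a minimum slot spacing of
#' `max(3 * burst_width_ms, window_guard_ms)` laid down jointly across the
#' two channels, so channel-exclusive bursts never fall inside another
#' channel's coincidence window (the dilute regime the assay assumes). A
#' `coincident_fraction` of bursts share a center time across channels, the
#' partner jittered by up to `jitter_ms`; the rest are channel-exclusive.
#'
#' @param truth A [tccd_truth()] object.
#' @param bin_width_ms Bin width in milliseconds.
#' @param seed Integer seed.
#' @param jitter_ms Maximum inter-channel center-time jitter of coincident
#'   bursts, ms.
#' @param window_guard_ms Minimum spacing between distinct burst slots, ms.
#'   The default keeps same-channel bursts resolvable at the analysis-side
#'   40-ms minimum peak separation (with margin for jitter) and exclusive
#'   bursts outside the 10-ms coincidence window.
#' @param channels Labels for the two output traces.
#' @return A list with traces `a` and `b` ([photon_trace()]) and `truth`,
#'   a list of burst center times `times_a_ms`, `times_b_ms`,
#'   `coincident_a_ms`, `coincident_b_ms`.
#' @export
gen_photon_pair <- function(truth = tccd_truth(), bin_width_ms = 1, seed,
                            jitter_ms = 2, window_guard_ms = 45,
                            channels = c("donor", "acceptor")) {
  stopifnot(inherits(truth, "tccd_truth"))
  dur_ms <- truth$duration_s * 1000
  n <- truth$n_bursts_per_channel
  occupancy <- n * 3 * truth$burst_width_ms / dur_ms
  if (occupancy >= 0.2)
    stop_validation(paste0(
      "expected burst occupancy %.0f%% of bins exceeds the 20%% dilute-regime ",
      "limit; lower the burst rate or lengthen the trace"), 100 * occupancy)
  with_seed(seed, {
    n_coin <- round(truth$coincident_fraction * n)
    n_excl <- n - n_coin
    n_slots <- n_coin + 2L * n_excl
    gap <- max(3 * truth$burst_width_ms, window_guard_ms)
    span <- dur_ms - 2 * gap - (n_slots - 1) * gap
    if (n_slots > 0 && span <= 0)
      stop_validation("too many bursts for the trace duration; lower the burst rate")
    slots <- if (n_slots > 0)
      gap + sort(runif(n_slots, 0, span)) + (seq_len(n_slots) - 1) * gap
    else numeric(0)
    lab <- rep(c("coin", "a", "b"), c(n_coin, n_excl, n_excl))
    lab <- sample(lab)
    t_coin <- slots[lab == "coin"]
    jit <- if (jitter_ms > 0 && n_coin > 0)
      runif(n_coin, -jitter_ms, jitter_ms) else rep(0, n_coin)
    times_a <- sort(c(t_coin, slots[lab == "a"]))
    times_b <- sort(c(t_coin + jit, slots[lab == "b"]))

    n_bins <- round(dur_ms / bin_width_ms)
    centers <- (seq_len(n_bins) - 0.5) * bin_width_ms
    sigma <- truth$burst_width_ms / (2 * sqrt(2 * log(2)))
    burst_signal <- function(times) {
      sig <- numeric(n_bins)
      for (t0 in times) {
        lo <- max(1L, floor((t0 - 5 * sigma) / bin_width_ms))
        hi <- min(n_bins, ceiling((t0 + 5 * sigma) / bin_width_ms))
        idx <- lo:hi
        sig[idx] <- sig[idx] +
          truth$burst_amplitude * exp(-(centers[idx] - t0)^2 / (2 * sigma^2))
      }
      sig
    }
    make_counts <- function(times) {
      bg <- pmax(0, rnorm(n_bins, truth$bg_mean, truth$bg_sd))
      round(bg + burst_signal(times))
    }
    list(a = photon_trace(make_counts(times_a), bin_width_ms, channels[1]),
         b = photon_trace(make_counts(times_b), bin_width_ms, channels[2]),
         truth = list(times_a_ms = times_a, times_b_ms = times_b,
                      coincident_a_ms = sort(t_coin),
                      coincident_b_ms = sort(t_coin + jit)))
  })
}

# ---- turbidity --------------------------------------------------------------

#' Generate a synthetic saturating turbidity series
#'
#' Optical density follows `od_max * (1 - exp(-rate * t))` per wavelength,
#' scaled by `wavelength_factors` (light scattering falls with wavelength),
#' plus Gaussian noise.
#'
#' @param od_max Saturating OD at the reference wavelength (non-negative).
#' @param rate_per_s Exponential approach rate, 1/s.
#' @param noise_sd Gaussian noise, OD units.
#' @param duration_s Total duration, seconds.
#' @param dt_s Sampling interval, seconds. The default 10-s interval over
#'   300 s gives 30 readings.
#' @param wavelength_factors Named scale factors per wavelength label.
#' @param seed Integer seed.
#' @param well_id Well label.
#' @return A [turbidity_series()] object.
#' @export
gen_turbidity_series <- function(od_max = 0.5, rate_per_s = 0.02,
                                 noise_sd = 0.005, duration_s = 300,
                                 dt_s = 10,
                                 wavelength_factors = c("340" = 1,
                                                        "400" = 0.7,
                                                        "600" = 0.4),
                                 seed, well_id = "A1") {
  assert_scalar_number(od_max, "od_max", lower = 0)
  with_seed(seed, {
    time_s <- seq(dt_s, by = dt_s, length.out = floor(duration_s / dt_s))
    od <- lapply(wavelength_factors, function(f) {
      mu <- f * od_max * (1 - exp(-rate_per_s * time_s))
      mu + if (noise_sd > 0) rnorm(length(time_s), 0, noise_sd) else 0
    })
    turbidity_series(well_id, time_s, as.data.frame(od, check.names = FALSE,
                                                    optional = TRUE))
  })
}
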
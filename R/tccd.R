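# tccd module: two-color coincidence detection. Noise model from a Gaussian
# fit to the photon-count-rate histogram, thresholded peak finding with a
# minimum separation, greedy one-to-one inter-channel matching, and percent
# coincidence relative to a reference channel.

FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))  # 2.354820045...

#' Fit the background noise model of a photon trace
#'
#' Fits a Gaussian to the histogram of per-bin counts by least squares. The
#' histogram is dominated by the background mode, so rare burst bins in the
#' upper tail barely perturb the fit. From the fitted center and width the
#' detection threshold is derived as
#' `threshold = p_center + 2 * FWHM`, with `FWHM = 2 sqrt(2 ln 2) * sigma`.
#'
#' Histogram binning uses the Freedman-Diaconis rule, widened to at least
#' one count for integer data so the histogram cannot comb.
#'
#' @param trace A [photon_trace()] with at least 100 bins.
#' @return An object of class `noise_model`: `p_center`, `sigma`, `fwhm`,
#'   `threshold`.
#' @export
fit_noise <- function(trace) {
  stopifnot(inherits(trace, "photon_trace"))
  x <- trace$counts
  if (sd(x) == 0)
    stop_validation("degenerate noise: photon counts have zero variance")
  fd <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  width <- max(1, round(fd))
  breaks <- seq(floor(min(x)) - 0.5, ceiling(max(x)) + width, by = width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  xs <- h$mids
  ys <- h$counts
  mode0 <- xs[which.max(ys)]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ys ~ A * exp(-(xs - mu)^2 / (2 * sg^2)),
      start = list(A = max(ys), mu = mode0, sg = max(sd(x), width / 2)),
      lower = c(A = 0, mu = -Inf, sg = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop_validation("noise fit failed: %s", conditionMessage(fit))
  cf <- coef(fit)
  p_center <- unname(cf["mu"])
  sigma <- abs(unname(cf["sg"]))
  fwhm <- FWHM_PER_SIGMA * sigma
  structure(list(p_center = p_center, sigma = sigma, fwhm = fwhm,
                 threshold = p_center + 2 * fwhm),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf(
    "<noise_model> center %.3f, sigma %.3f, FWHM %.3f, threshold %.3f\n",
    x$p_center, x$sigma, x$fwhm, x$threshold))
  invisible(x)
}

#' Find above-threshold peaks in a photon trace
#'
#' Local maxima whose counts exceed the noise threshold, kept greedily in
#' descending height order subject to a minimum separation between peaks
#' (slowly diffusing species spread over several bins must count once).
#' Peak times are bin centers.
#'
#' @param trace A [photon_trace()].
#' @param noise A [fit_noise()] result (or any list with a `threshold`).
#' @param min_separation_ms Minimum time between reported peaks, ms.
#' @return An object of class `peak_set`: `times_ms` (strictly increasing),
#'   `heights` (maximum counts per peak), `channel`, `threshold`,
#'   `duration_ms`. Empty sets are allowed.
#' @export
find_peaks <- function(trace, noise, min_separation_ms = 40) {
  stopifnot(inherits(trace, "photon_trace"))
  x <- as.numeric(trace$counts)
  n <- length(x)
  thr <- noise$threshold
  left <- c(-Inf, x[-n])
  right <- c(x[-1], -Inf)
  # plateau tie-break: keep the first bin of a flat-topped peak
  cand <- which(x > thr & x > left & x >= right)
  ord <- cand[order(x[cand], decreasing = TRUE)]
  times <- (cand - 0.5) * trace$bin_width_ms
  names(times) <- cand
  min_sep_bins <- min_separation_ms / trace$bin_width_ms
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0L || all(abs(kept - i) >= min_sep_bins))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  structure(list(times_ms = (kept - 0.5) * trace$bin_width_ms,
                 heights = x[kept], channel = trace$channel,
                 threshold = thr,
                 duration_ms = n * trace$bin_width_ms),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> channel '%s': %d peak(s) above %.2f\n",
              x$channel, length(x$times_ms), x$threshold))
  invisible(x)
}

#' Two-channel coincidence of peak sets
#'
#' Candidate pairs are peaks from the two channels within `window_ms` of
#' each other; they are matched greedily by smallest inter-channel time
#' difference with each peak used at most once. The matching is symmetric in
#' the two channels and optimal whenever candidate pairs do not compete for
#' a peak. Percent coincidence is reported relative to the designated
#' reference channel:
#' `percent = 100 * n_pairs / n_reference_peaks`.
#'
#' @param a,b [find_peaks()] results for the two channels.
#' @param window_ms Coincidence window in milliseconds.
#' @param reference Which channel's peak count normalizes the percentage:
#'   `"a"` or `"b"`, or one of the channels' labels.
#' @return An object of class `coincidence_result`: `coincident_pairs`
#'   (two-column matrix of times), `n_a`, `n_b`, `n_coincident`,
#'   `percent_coincident_ref`, `reference`, `defined` (FALSE when the
#'   reference channel has no peaks, in which case the percentage is NA, not
#'   zero).
#' @export
coincidence <- function(a, b, window_ms = 10, reference = "a") {
  stopifnot(inherits(a, "peak_set"), inherits(b, "peak_set"))
  if (!isTRUE(all.equal(a$duration_ms, b$duration_ms)))
    stop_validation("peak sets come from traces of different duration")
  ref <- if (reference %in% c("a", "b")) reference
         else if (identical(reference, a$channel)) "a"
         else if (identical(reference, b$channel)) "b"
         else stop_validation("unknown reference channel '%s'", reference)

  ta <- a$times_ms
  tb <- b$times_ms
  pairs <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("time_a_ms", "time_b_ms")))
  if (length(ta) && length(tb)) {
    dt <- abs(outer(ta, tb, `-`))
    cand <- which(dt <= window_ms, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(dt[cand]), , drop = FALSE]
      used_a <- logical(length(ta))
      used_b <- logical(length(tb))
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        ia <- cand[i, 1]; ib <- cand[i, 2]
        if (!used_a[ia] && !used_b[ib]) {
          used_a[ia] <- TRUE; used_b[ib] <- TRUE; keep[i] <- TRUE
        }
      }
      m <- cand[keep, , drop = FALSE]
      pairs <- cbind(time_a_ms = ta[m[, 1]], time_b_ms = tb[m[, 2]])
      pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    }
  }
  n_ref <- if (ref == "a") length(ta) else length(tb)
  structure(
    list(coincident_pairs = pairs, n_a = length(ta), n_b = length(tb),
         n_coincident = nrow(pairs),
         percent_coincident_ref =
           if (n_ref > 0) 100 * nrow(pairs) / n_ref else NA_real_,
         reference = ref, defined = n_ref > 0),
    class = "coincidence_result")
}

#' @export
print.coincidence_result <- function(x, ...) {
  cat(sprintf(
    "<coincidence_result> %d / (%d a, %d b) peaks coincident; %% vs '%s' = %s\n",
    x$n_coincident, x$n_a, x$n_b, x$reference,
    if (x$defined) sprintf("%.1f", x$percent_coincident_ref)
    else "undefined (no reference peaks)"))
  invisible(x)
}

#' Monte-Carlo chance-coincidence diagnostic
#'
#' Estimates the percent coincidence expected if the two channels' peak
#' times were independent, by re-drawing one channel's peak times uniformly
#' (respecting the minimum separation) and re-matching. No correction is
#' applied to the measured percentage; this is a diagnostic column only.
#'
#' @param a,b [find_peaks()] results.
#' @param window_ms Coincidence window, ms.
#' @param reference Reference channel, as in [coincidence()].
#' @param n_mc Monte-Carlo draws.
#' @param min_separation_ms Minimum spacing preserved when re-drawing.
#' @param seed Integer seed.
#' @return Mean chance percent coincidence over the draws (NA if the
#'   reference channel has no peaks).
#' @export
chance_coincidence <- function(a, b, window_ms = 10, reference = "a",
                               n_mc = 100, min_separation_ms = 40, seed = 1) {
  stopifnot(inherits(a, "peak_set"), inherits(b, "peak_set"))
  if (length(a$times_ms) == 0 || length(b$times_ms) == 0) return(NA_real_)
  with_seed(seed, {
    draws <- vapply(seq_len(n_mc), function(i) {
      nb <- length(b$times_ms)
      g <- min_separation_ms
      span <- b$duration_ms - nb * g
      if (span <= 0) return(NA_real_)
      tb <- sort(runif(nb, 0, span)) + (seq_len(nb) - 1) * g + g / 2
      b2 <- b
      b2$times_ms <- tb
      coincidence(a, b2, window_ms, reference)$percent_coincident_ref
    }, numeric(1))
    mean(draws, na.rm = TRUE)
  })
}
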
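# tht_kinetics module: Boltzmann-sigmoid fitting of ThT traces and the
# kinetic summaries derived from it (elongation rate, lag time, endpoint,
# percent protection, per-well aggregation events).

#' Fit a ThT trace to the Boltzmann sigmoid
#'
#' Fits `F(t) = Fi + (Ff - Fi) / (1 + exp((t50 - t) / k))` by nonlinear least
#' squares. Starting values: `Fi` from the mean of the first 5% of points,
#' `Ff` from the last 5%, `t50` where the trace first crosses the midpoint,
#' `k` at one twentieth of the observed time span. No box constraints are
#' imposed; the sign of the fitted `k` conveys direction, but a fit is only
#' reported as converged when it describes a rising sigmoid (`k > 0`) with
#' midpoint inside the observed range (within one span) and adequate
#' goodness of fit.
#'
#' @param trace A [tht_trace()] object with at least 10 points.
#' @param min_r2 Minimum r-squared below which the fit is flagged
#'   non-converged.
#' @param noise_floor Intensity standard deviation at or below which the
#'   trace is declared transition-free without fitting.
#' @return An object of class `boltzmann_fit` with elements `Fi`, `Ff`,
#'   `t50_s`, `k_s`, `param_se`, `r2`, `converged` and `reason`.
#' @export
#' @examples
#' sim <- gen_tht_plate(tht_truth(noise_sd = 0, lag_cv = 0), n_wells = 1,
#'                      seed = 7)
#' fit_boltzmann(sim$plate$traces[[1]])
fit_boltzmann <- function(trace, min_r2 = 0.5, noise_floor = 0) {
  stopifnot(inherits(trace, "tht_trace"))
  t <- trace$time_s
  y <- trace$intensity
  out <- structure(
    list(Fi = NA_real_, Ff = NA_real_, t50_s = NA_real_, k_s = NA_real_,
         param_se = c(Fi = NA_real_, Ff = NA_real_, t50 = NA_real_,
                      k = NA_real_),
         r2 = NA_real_, converged = FALSE, reason = ""),
    class = "boltzmann_fit")

  if (sd(y) <= noise_floor) {
    out$reason <- "no transition"
    return(out)
  }

  n <- length(y)
  n_edge <- max(2L, ceiling(0.05 * n))
  Fi0 <- mean(head(y, n_edge))
  Ff0 <- mean(tail(y, n_edge))
  mid <- (Fi0 + Ff0) / 2
  cross <- if (Ff0 >= Fi0) which(y >= mid)[1] else which(y <= mid)[1]
  t50_0 <- if (is.na(cross)) mean(range(t)) else t[cross]
  k0 <- diff(range(t)) / 20

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ Fi + (Ff - Fi) / (1 + exp((t50 - t) / k)),
      start = list(Fi = Fi0, Ff = Ff0, t50 = t50_0, k = k0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out$reason <- paste("optimizer failure:", conditionMessage(fit))
    return(out)
  }

  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  out$Fi <- unname(cf["Fi"]); out$Ff <- unname(cf["Ff"])
  out$t50_s <- unname(cf["t50"]); out$k_s <- unname(cf["k"])
  out$param_se <- setNames(as.numeric(se), c("Fi", "Ff", "t50", "k"))
  out$r2 <- r_squared(y, predict(fit))

  span <- diff(range(t))
  if (!is.finite(out$r2) || out$r2 < min_r2) {
    out$reason <- sprintf("poor fit (r2 = %.3f)", out$r2)
  } else if (out$k_s <= 0) {
    out$reason <- "decreasing fit (k <= 0)"
  } else if (out$t50_s < min(t) - span || out$t50_s > max(t) + span) {
    out$reason <- "midpoint outside observed range"
  } else {
    out$converged <- TRUE
  }
  out
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "<boltzmann_fit> Fi = %.4g, Ff = %.4g, t50 = %.4g s, k = %.4g s (r2 = %.4f)\n",
      x$Fi, x$Ff, x$t50_s, x$k_s, x$r2))
  else
    cat(sprintf("<boltzmann_fit> not converged: %s\n", x$reason))
  invisible(x)
}

#' Kinetic summaries from a Boltzmann fit
#'
#' Computes the derived quantities of a sigmoidal fibrillation curve:
#'
#' * elongation rate `(Ff - Fi) / (4 k)` -- the maximal slope, attained at
#'   the midpoint `t50`;
#' * `t_lag_paper_s = 4 k Fi / (Ff - Fi) + t50 - 2 k` -- the lag time from
#'   intersecting the midpoint tangent with `F = Fi`, carrying a
#'   baseline-dependent term;
#' * `t_lag_tangent_s = t50 - 2 k` -- the classical tangent construction
#'   intersecting `F = 0`'s baseline-free form. The two coincide exactly
#'   when `Fi = 0`;
#' * `endpoint` -- mean of the final three observed points (robust to a
#'   last-cycle artifact), reported from the raw trace, not the fitted
#'   plateau;
#' * `delta_I = Ff - Fi` -- the fitted fluorescence amplitude.
#'
#' @param fit A converged [fit_boltzmann()] result.
#' @param trace The fitted [tht_trace()] (for the raw endpoint).
#' @return An object of class `kinetic_summary`.
#' @export
kinetic_summary <- function(fit, trace) {
  stopifnot(inherits(fit, "boltzmann_fit"))
  if (!fit$converged)
    stop_validation("kinetic_summary requires a converged fit (%s)", fit$reason)
  amp <- fit$Ff - fit$Fi
  if (amp == 0)
    stop_validation("Ff equals Fi: lag time undefined (division by zero)")
  structure(
    list(elongation_rate = amp / (4 * fit$k_s),
         t_lag_paper_s = 4 * fit$k_s * fit$Fi / amp + fit$t50_s - 2 * fit$k_s,
         t_lag_tangent_s = fit$t50_s - 2 * fit$k_s,
         endpoint = mean(tail(trace$intensity, 3)),
         delta_I = amp),
    class = "kinetic_summary")
}

#' @export
print.kinetic_summary <- function(x, ...) {
  cat(sprintf(
    "<kinetic_summary> elongation %.4g a.u./s, lag %.4g s (tangent %.4g s), dI %.4g\n",
    x$elongation_rate, x$t_lag_paper_s, x$t_lag_tangent_s, x$delta_I))
  invisible(x)
}

#' Percent protection conferred by a chaperone
#'
#' `%Protection = (dI - dI_chaperone) / dI * 100`, where `dI` is the ThT
#' amplitude of the substrate alone and `dI_chaperone` its amplitude in the
#' chaperone's presence. Values may be negative when the chaperone increases
#' the fluorescence amplitude.
#'
#' @param delta_I_ref Amplitude of the substrate alone (non-zero).
#' @param delta_I_chaperone Amplitude in the presence of the chaperone.
#' @return Percentage, possibly negative.
#' @export
#' @examples
#' percent_protection(1000, 0)    # 100
#' percent_protection(1000, 1500) # -50
percent_protection <- function(delta_I_ref, delta_I_chaperone) {
  assert_scalar_number(delta_I_ref, "delta_I_ref")
  assert_scalar_number(delta_I_chaperone, "delta_I_chaperone")
  if (delta_I_ref == 0)
    stop_validation("reference amplitude is zero: protection undefined")
  (delta_I_ref - delta_I_chaperone) / delta_I_ref * 100
}

#' Event-coding criteria for per-well aggregation calls
#'
#' An aggregation event requires a converged sigmoid whose amplitude exceeds
#' `min_fold` times the noise of the first `n_baseline` points and whose fit
#' reaches `min_r2`. Wells failing any criterion are right-censored at the
#' final assay time.
#'
#' @param min_fold Minimum amplitude as a multiple of the baseline standard
#'   deviation.
#' @param n_baseline Number of initial points defining the baseline noise.
#' @param min_r2 Minimum fit r-squared for an event call.
#' @param lag_formula Which lag time stamps the event: `"paper"`
#'   (baseline-dependent form, default) or `"tangent"` (`t50 - 2k`).
#' @return An object of class `event_criteria`.
#' @export
event_criteria <- function(min_fold = 10, n_baseline = 10, min_r2 = 0.9,
                           lag_formula = c("paper", "tangent")) {
  structure(list(min_fold = min_fold, n_baseline = as.integer(n_baseline),
                 min_r2 = min_r2, lag_formula = match.arg(lag_formula)),
            class = "event_criteria")
}

#' Code one well as an aggregation event or censored observation
#'
#' @param trace A [tht_trace()] object.
#' @param fit Optional [fit_boltzmann()] result for the trace (computed if
#'   missing).
#' @param criteria An [event_criteria()] object.
#' @return An `event_record`: list with `well_id`, `event` (0/1) and
#'   `time_s` (lag time if an event, final assay time if censored; event
#'   times are clipped to stay positive).
#' @export
detect_event <- function(trace, fit = NULL, criteria = event_criteria()) {
  stopifnot(inherits(trace, "tht_trace"), inherits(criteria, "event_criteria"))
  if (is.null(fit)) fit <- fit_boltzmann(trace)
  baseline_sd <- sd(head(trace$intensity, criteria$n_baseline))
  is_event <- fit$converged &&
    (fit$Ff - fit$Fi) > criteria$min_fold * baseline_sd &&
    fit$r2 >= criteria$min_r2
  if (is_event) {
    s <- kinetic_summary(fit, trace)
    lag <- if (criteria$lag_formula == "paper") s$t_lag_paper_s
           else s$t_lag_tangent_s
    time_s <- max(lag, min(diff(trace$time_s)) / 2)  # clip to > 0
    event <- 1L
  } else {
    time_s <- max(trace$time_s)
    event <- 0L
  }
  structure(list(well_id = trace$well_id, event = event, time_s = time_s),
            class = "event_record")
}

#' Fit and summarize every well of a kinetic plate
#'
#' Runs [fit_boltzmann()], [kinetic_summary()] and [detect_event()] over all
#' wells and assembles a tidy one-row-per-well table.
#'
#' @param plate A [plate_kinetics()] object.
#' @param criteria An [event_criteria()] object.
#' @param ... Passed to [fit_boltzmann()].
#' @return Data frame with fit parameters, kinetic summaries and event
#'   coding per well.
#' @export
analyze_plate <- function(plate, criteria = event_criteria(), ...) {
  stopifnot(inherits(plate, "plate_kinetics"))
  rows <- lapply(plate$traces, function(tr) {
    fit <- fit_boltzmann(tr, ...)
    ev <- detect_event(tr, fit, criteria)
    s <- if (fit$converged && fit$Ff != fit$Fi) kinetic_summary(fit, tr)
         else NULL
    data.frame(
      well_id = tr$well_id, condition = tr$condition,
      converged = fit$converged, r2 = fit$r2,
      Fi = fit$Fi, Ff = fit$Ff, t50_s = fit$t50_s, k_s = fit$k_s,
      elongation_rate = s$elongation_rate %||% NA_real_,
      t_lag_paper_s = s$t_lag_paper_s %||% NA_real_,
      t_lag_tangent_s = s$t_lag_tangent_s %||% NA_real_,
      endpoint = mean(tail(tr$intensity, 3)),
      delta_I = s$delta_I %||% NA_real_,
      raw_delta_I = max(tr$intensity) -
        mean(head(tr$intensity, criteria$n_baseline)),
      event = ev$event, time_s = ev$time_s,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-condition percent-protection table
#'
#' Averages the fluorescence amplitude `delta_I` within each condition and
#' expresses every condition's amplitude as percent protection relative to
#' the reference condition (the substrate alone). Converged wells contribute
#' their fitted amplitude `Ff - Fi`; wells without a converged fit
#' contribute the raw amplitude (trace maximum minus baseline mean), so
#' fully suppressed wells count as strong protection rather than being
#' dropped.
#'
#' @param results Data frame from [analyze_plate()], with `condition`,
#'   `delta_I` and `raw_delta_I` columns.
#' @param reference Condition label of the substrate-alone wells.
#' @return Data frame with `condition`, `mean_delta_I`, `n` and
#'   `percent_protection`.
#' @export
protection_table <- function(results, reference) {
  stopifnot(is.data.frame(results), "condition" %in% names(results))
  if (!reference %in% results$condition)
    stop_validation("reference condition '%s' not present", reference)
  amp <- ifelse(is.na(results$delta_I), results$raw_delta_I,
                results$delta_I)
  agg <- aggregate(amp, by = list(condition = results$condition),
                   FUN = mean)
  names(agg)[2] <- "mean_delta_I"
  agg$n <- as.vector(table(results$condition)[agg$condition])
  ref_amp <- agg$mean_delta_I[agg$condition == reference]
  agg$percent_protection <- vapply(
    agg$mean_delta_I, function(a) percent_protection(ref_amp, a), numeric(1))
  agg
}
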
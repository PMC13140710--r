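# surv module: Kaplan-Meier estimation, log-rank (Mantel-Cox) testing,
# hazard ratios and mean time to failure for per-well aggregation events.

#' Per-well aggregation event table
#'
#' @param well_id Character vector of well labels.
#' @param event Integer vector, 1 for an aggregation event, 0 for a
#'   right-censored well.
#' @param time_s Positive event (lag) or censoring times in seconds.
#' @param group Single condition label for the table.
#' @return An object of class `event_table` (a data frame).
#' @export
event_table <- function(well_id, event, time_s, group = "group") {
  if (length(well_id) == 0L)
    stop_validation("an event table needs at least one record")
  if (!all(event %in% c(0L, 1L)))
    stop_validation("event must be coded 0/1")
  if (any(!is.finite(time_s)) || any(time_s <= 0))
    stop_validation("all event/censor times must be positive")
  structure(data.frame(well_id = as.character(well_id),
                       event = as.integer(event),
                       time_s = as.numeric(time_s),
                       group = as.character(group),
                       stringsAsFactors = FALSE),
            class = c("event_table", "data.frame"))
}

#' Collect detect_event results into an event table
#'
#' @param records List of `event_record` objects from [detect_event()].
#' @param group Condition label.
#' @return An [event_table()].
#' @export
as_event_table <- function(records, group = "group") {
  event_table(vapply(records, `[[`, character(1), "well_id"),
              vapply(records, `[[`, integer(1), "event"),
              vapply(records, `[[`, numeric(1), "time_s"),
              group = group)
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored product-limit estimator of the probability that a well has
#' not yet aggregated; ties are handled as simultaneous events at the shared
#' time. A table with no events at all yields the degenerate flat curve at 1
#' and is flagged.
#'
#' @param table An [event_table()].
#' @return An object of class `km_curve`: `times` (unique event times),
#'   `survival`, `at_risk`, `n_events`, `n`, `degenerate`.
#' @export
#' @examples
#' tab <- event_table(paste0("W", 1:4), c(1, 1, 0, 0), c(2, 4, 5, 5))
#' km_estimate(tab)$survival  # 0.75, 0.50
km_estimate <- function(table) {
  stopifnot(inherits(table, "event_table"))
  fit <- survival::survfit(
    survival::Surv(time_s, event) ~ 1,
    data = as.data.frame(table), conf.type = "none")
  keep <- fit$n.event > 0
  structure(
    list(times = fit$time[keep], survival = fit$surv[keep],
         at_risk = fit$n.risk[keep], n_events = fit$n.event[keep],
         n = nrow(table), degenerate = !any(table$event == 1L)),
    class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d event time(s)%s\n", x$n,
              length(x$times), if (x$degenerate) " [degenerate: no events]"
              else ""))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve as a step function
#'
#' @param curve A `km_curve`.
#' @param t Times at which to evaluate the survival step function.
#' @return Survival probabilities (1 before the first event).
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(ti) {
    i <- which(curve$times <= ti)
    if (length(i) == 0L) 1 else curve$survival[max(i)]
  }, numeric(1))
}

#' Log-rank (Mantel-Cox) test with hazard ratio
#'
#' Mantel-Cox chi-square over the pooled event times with one degree of
#' freedom. The hazard ratio of group `a` relative to group `b` is the ratio
#' of observed-to-expected event counts, `(O_a / E_a) / (O_b / E_b)`, with a
#' 95% confidence interval from the normal approximation on the log hazard
#' scale (`se = sqrt(1/E_a + 1/E_b)`). When group `b` has no events the
#' hazard ratio is `+Inf` and flagged.
#'
#' @param a,b [event_table()] objects for the two groups.
#' @return An object of class `logrank_result`: `chi2`, `p`,
#'   `hazard_ratio`, `hr_ci95`, `observed`, `expected`, `hr_defined`.
#' @export
logrank_test <- function(a, b) {
  stopifnot(inherits(a, "event_table"), inherits(b, "event_table"))
  pooled <- rbind(
    data.frame(time_s = a$time_s, event = a$event, grp = "a"),
    data.frame(time_s = b$time_s, event = b$event, grp = "b"))
  if (sum(pooled$event) == 0L)
    stop_validation("no events in either group: log-rank undefined")
  sd_ <- survival::survdiff(survival::Surv(time_s, event) ~ grp,
                            data = pooled)
  chi2 <- unname(sd_$chisq)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  O <- as.numeric(sd_$obs)
  E <- as.numeric(sd_$exp)
  hr_defined <- O[2] > 0
  hr <- if (hr_defined) (O[1] / E[1]) / (O[2] / E[2]) else Inf
  se_log <- sqrt(1 / E[1] + 1 / E[2])
  ci <- if (hr_defined && hr > 0)
    exp(log(hr) + c(-1, 1) * qnorm(0.975) * se_log)
  else c(NA_real_, NA_real_)
  structure(
    list(chi2 = chi2, p = p, hazard_ratio = hr, hr_ci95 = ci,
         observed = setNames(O, c("a", "b")),
         expected = setNames(E, c("a", "b")), hr_defined = hr_defined),
    class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf(
    "<logrank_result> chi2 = %.4g, p = %.4g, HR(a/b) = %.4g [%.4g, %.4g]\n",
    x$chi2, x$p, x$hazard_ratio, x$hr_ci95[1], x$hr_ci95[2]))
  invisible(x)
}

#' Pairwise log-rank comparisons across conditions
#'
#' Runs [logrank_test()] for every condition against the reference and
#' adjusts p-values with Holm's method (the comparisons are a family of
#' pairwise tests against a common control).
#'
#' @param tables Named list of [event_table()] objects.
#' @param reference Name of the reference table.
#' @param p_adjust Adjustment method passed to [stats::p.adjust()].
#' @return Data frame: `condition`, `chi2`, `p`, `p_adj`, `hazard_ratio`,
#'   `hr_lo`, `hr_hi`.
#' @export
pairwise_logrank <- function(tables, reference, p_adjust = "holm") {
  stopifnot(is.list(tables), reference %in% names(tables))
  others <- setdiff(names(tables), reference)
  rows <- lapply(others, function(nm) {
    lr <- logrank_test(tables[[nm]], tables[[reference]])
    data.frame(condition = nm, chi2 = lr$chi2, p = lr$p,
               hazard_ratio = lr$hazard_ratio,
               hr_lo = lr$hr_ci95[1], hr_hi = lr$hr_ci95[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out[, c("condition", "chi2", "p", "p_adj", "hazard_ratio", "hr_lo",
          "hr_hi")]
}

#' Mean time to failure from a Kaplan-Meier curve
#'
#' Fits the decreasing sigmoid
#' `S(t) = Sf + (1 - Sf) / (1 + exp((t - t50) / k))` (upper plateau fixed at
#' 1, lower plateau free) to the product-limit step function and returns the
#' tangent-construction onset `t50 - 2 |k|`. The survival curve starts at 1,
#' so the baseline-dependent lag form does not apply; the tangent form is
#' the geometrically meaningful onset here.
#'
#' @param curve A `km_curve` with at least 3 distinct event times.
#' @return List with `mttf_s` (NA with a reason when undefined), `t50_s`,
#'   `k_s`, `converged`, `reason`.
#' @export
mean_time_to_failure <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  fail <- function(reason) list(mttf_s = NA_real_, t50_s = NA_real_,
                                k_s = NA_real_, converged = FALSE,
                                reason = reason)
  if (curve$degenerate) return(fail("no events (all censored)"))
  if (length(curve$times) < 3L)
    return(fail(sprintf("only %d distinct event time(s); need 3",
                        length(curve$times))))
  t <- c(0, curve$times)
  s <- c(1, curve$survival)
  t50_0 <- curve$times[which(curve$survival <= 0.5)[1]]
  if (is.na(t50_0)) t50_0 <- max(curve$times)
  k0 <- max(diff(range(t)) / 20, .Machine$double.eps)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      s ~ Sf + (1 - Sf) / (1 + exp((t - t50) / k)),
      start = list(Sf = min(s), t50 = t50_0, k = k0),
      lower = c(Sf = 0, t50 = 0, k = 1e-12),
      upper = c(Sf = 0.999, t50 = Inf, k = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(fail(paste("optimizer failure:", conditionMessage(fit))))
  cf <- coef(fit)
  list(mttf_s = unname(cf["t50"] - 2 * abs(cf["k"])),
       t50_s = unname(cf["t50"]), k_s = unname(cf["k"]),
       converged = TRUE, reason = "")
}
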
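# Independent oracles and fixture builders used across the test files.
# These deliberately re-derive results by brute force (direct enumeration,
# closed forms) and never call the implementation they check.

# product-limit estimator by direct enumeration
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  list(times = ut, survival = surv)
}

# Mantel-Cox statistic by enumerating the 2x2 table at each pooled event time
logrank_oracle <- function(t1, e1, t2, e2) {
  time <- c(t1, t2)
  event <- c(e1, e2)
  grp1 <- c(rep(TRUE, length(t1)), rep(FALSE, length(t2)))
  ut <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  O2 <- 0; E2 <- 0
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp1)
    O1 <- O1 + d1; O2 <- O2 + (d - d1)
    E1 <- E1 + d * n1 / n
    E2 <- E2 + d * (n - n1) / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) (O1 - E1)^2 / V else 0
  list(chi2 = chi2, O = c(O1, O2), E = c(E1, E2),
       p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       hr = if (O2 > 0) (O1 / E1) / (O2 / E2) else Inf)
}

# random small right-censored dataset (integer times force ties)
random_event_data <- function(n, max_t = 6) {
  time <- sample(seq_len(max_t), n, replace = TRUE)
  event <- stats::rbinom(n, 1, 0.7)
  list(time = time, event = event)
}

# maximum-cardinality one-to-one matching within a window, by recursion
max_matching_oracle <- function(ta, tb, window) {
  cand <- which(abs(outer(ta, tb, `-`)) <= window, arr.ind = TRUE)
  if (nrow(cand) == 0) return(0L)
  best <- 0L
  recurse <- function(i, used_a, used_b, size) {
    if (i > nrow(cand)) {
      best <<- max(best, size)
      return(invisible())
    }
    ia <- cand[i, 1]; ib <- cand[i, 2]
    if (!used_a[ia] && !used_b[ib]) {
      used_a[ia] <- TRUE; used_b[ib] <- TRUE
      recurse(i + 1L, used_a, used_b, size + 1L)
      used_a[ia] <- FALSE; used_b[ib] <- FALSE
    }
    recurse(i + 1L, used_a, used_b, size)
  }
  recurse(1L, logical(length(ta)), logical(length(tb)), 0L)
  best
}

# closed-form Boltzmann evaluated directly (generator-independent)
boltzmann_closed_form <- function(t, Fi, Ff, t50, k) {
  Fi + (Ff - Fi) / (1 + exp((t50 - t) / k))
}

# a minimal converged fit object for exercising summary algebra
make_fit <- function(Fi, Ff, t50, k) {
  structure(list(Fi = Fi, Ff = Ff, t50_s = t50, k_s = k,
                 param_se = c(Fi = 0, Ff = 0, t50 = 0, k = 0),
                 r2 = 1, converged = TRUE, reason = ""),
            class = "boltzmann_fit")
}

flat_trace <- function(n = 30, level = 100, well = "A1") {
  tht_trace(well, 350 * (0:(n - 1)), rep(level, n))
}
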
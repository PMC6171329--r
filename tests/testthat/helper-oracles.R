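# Independent brute-force oracles: explicit loops, no shared code with the
# package internals they check.

# Product-limit estimator by explicit loop over risk sets.
bf_km <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = et, survival = NA_real_)
  for (k in seq_along(et)) {
    n_risk <- sum(time >= et[k])
    d <- sum(time == et[k] & event == 1)
    s <- s * (1 - d / n_risk)
    out$survival[k] <- s
  }
  out
}

# Log-rank O, E, V by explicit enumeration over event times; returns the
# signed standardized statistic for the `high` group and the chi-square.
bf_logrank <- function(time, event, high) {
  et <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & high)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & high)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  z <- if (V > 0) (O - E) / sqrt(V) else 0
  list(z = z, chisq = z^2)
}

# Exhaustive maxstat: evaluate bf_logrank at every admissible split,
# midpoint cutpoints, first maximum wins (lowest cutpoint).
bf_maxstat <- function(time, event, x, min_prop = 0.1) {
  v <- sort(unique(x))
  best <- NULL
  for (m in seq_len(length(v) - 1)) {
    high <- x > v[m]
    prop_low <- mean(!high)
    if (prop_low < min_prop || prop_low > 1 - min_prop) next
    r <- bf_logrank(time, event, high)
    if (is.null(best) || abs(r$z) > best$statistic + 1e-12) {
      best <- list(cutpoint = (v[m] + v[m + 1]) / 2, statistic = abs(r$z),
                   chisq = r$z^2, n_low = sum(!high), n_high = sum(high))
    }
  }
  best
}

# Efron-tie Cox partial log-likelihood for one covariate, written directly
# from the definition.
bf_efron_loglik <- function(beta, time, event, x) {
  et <- sort(unique(time[event == 1]))
  ll <- 0
  for (t in et) {
    risk <- which(time >= t)
    dead <- which(time == t & event == 1)
    d <- length(dead)
    eta <- x[risk] * beta
    ll <- ll + sum(x[dead]) * beta
    sum_risk <- sum(exp(eta))
    sum_dead <- sum(exp(x[dead] * beta))
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_risk - (l / d) * sum_dead)
    }
  }
  ll
}

# Simulated cohort with a binary covariate of known hazard ratio.
sim_binary_cohort <- function(n, hr, censor_rate = 0.01, base_rate = 0.03) {
  x <- rbinom(n, 1, 0.5)
  t_event <- rexp(n, rate = base_rate * hr^x)
  t_cens <- rexp(n, rate = censor_rate)
  data.frame(sample_id = sprintf("s%04d", seq_len(n)),
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens), x = x)
}

# Random right-censored cohort with no covariate effect.
sim_null_cohort <- function(n, event_prob = 0.7) {
  tibble::tibble(time = rexp(n, 0.05),
                 event = rbinom(n, 1, event_prob))
}
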
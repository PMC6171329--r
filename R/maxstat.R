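# Maximally selected rank statistics for survival cutpoint discovery.
#
# At each admissible split "x > c" the two groups are compared with the
# standardized log-rank statistic (hypergeometric variance over risk sets);
# the selected cutpoint maximizes its absolute value, and the p-value is
# corrected for having scanned many cutpoints.

# Standardized log-rank statistic at every admissible split of x.
# Returns one row per candidate cutpoint (midpoints between consecutive
# distinct x values; `split_value` is the observed value defining "x > v").
logrank_scan <- function(time, event, x, min_prop = 0.1,
                         cutpoint_type = c("midpoint", "observed")) {
  cutpoint_type <- match.arg(cutpoint_type)
  n <- length(time)
  v <- sort(unique(x))
  if (length(v) < 2) abort("`x` must take at least two distinct values.")

  split_value <- v[-length(v)]
  n_high <- vapply(split_value, function(s) sum(x > s), integer(1))
  prop_low <- (n - n_high) / n
  keep <- prop_low >= min_prop & prop_low <= 1 - min_prop
  if (!any(keep)) abort("no admissible cutpoint under `min_prop`.")
  split_value <- split_value[keep]
  n_high <- n_high[keep]
  upper <- v[-1][keep]
  cuts <- if (cutpoint_type == "midpoint") (split_value + upper) / 2 else split_value

  et <- sort(unique(time[event == 1]))
  if (length(et) == 0) abort("maxstat needs at least one observed event.")
  # risk-set / event incidence matrices: rows = event times, cols = samples
  R <- outer(et, time, `<=`)
  D <- outer(et, time, `==`) & matrix(event == 1, nrow = length(et), ncol = n, byrow = TRUE)
  storage.mode(R) <- "double"
  storage.mode(D) <- "double"
  nj <- rowSums(R)
  dj <- rowSums(D)

  H <- outer(x, split_value, `>`)
  storage.mode(H) <- "double"
  N1 <- R %*% H                    # at-risk in high group, per event time x cut
  O <- colSums(D %*% H)            # observed events in high group
  E <- colSums(dj * N1 / nj)
  w <- ifelse(nj > 1, dj * (nj - dj) / ((nj - 1) * nj^2), 0)
  V <- colSums(w * N1 * (nj - N1))
  z <- ifelse(V > 0, (O - E) / sqrt(V), 0)

  tibble(cutpoint = cuts, split_value = split_value,
         n_low = n - n_high, n_high = n_high,
         prop_low = (n - n_high) / n,
         statistic = z, chisq = z^2)
}

# Improved-Bonferroni approximation (Lausen & Schumacher) for the maximum of
# |B(t)| / sqrt(t(1-t)) over the scanned proportion band [eps1, eps2].
# Floored at the single-split chi-square p, which the corrected p cannot
# undercut, and capped at 1.
p_maxstat_lausen <- function(b, eps1, eps2) {
  if (!is.finite(b) || b <= 0) return(1)
  p <- 4 * dnorm(b) / b +
    dnorm(b) * (b - 1 / b) * log((eps2 * (1 - eps1)) / (eps1 * (1 - eps2)))
  p <- max(p, pchisq(b^2, df = 1, lower.tail = FALSE))
  min(p, 1)
}

# Plain Bonferroni union bound over the scanned cutpoints: valid (and in
# small samples the only reliably conservative closed form, since the
# Brownian-bridge approximation can undercut the permutation null in the
# extreme tail).
p_maxstat_bonferroni <- function(b, n_cuts) {
  min(1, n_cuts * pchisq(b^2, df = 1, lower.tail = FALSE))
}

#' Maximally selected rank statistic cutpoint
#'
#' Scans every admissible split `x > c` of a continuous covariate, computes
#' the standardized log-rank statistic for each induced two-group survival
#' comparison, and returns the cutpoint with the maximal absolute statistic
#' together with a p-value corrected for the multiplicity of cutpoints.
#'
#' @inheritParams km_curve
#' @param x Numeric covariate (vector aligned with `surv` rows, or a column
#'   name); at least two distinct values must survive the `min_prop`
#'   restriction.
#' @param min_prop Minimum fraction of samples required on each side of an
#'   admissible split (default 0.10).
#' @param p_method Multiplicity correction for having scanned many
#'   cutpoints. `"bonferroni"` (default): plain union bound over the
#'   candidate cutpoints, conservative at every sample size.
#'   `"lausen"`: the Lausen-Schumacher Brownian-bridge approximation —
#'   sharper for large cohorts, but it can undercut the permutation null in
#'   the extreme tail of small cohorts. `"permutation"`: label-permutation
#'   estimate of P(max statistic >= observed). `"none"`: no p-value.
#' @param n_perm,seed Number of permutations and RNG seed for
#'   `p_method = "permutation"`.
#' @param cutpoint_type `"midpoint"` reports the midpoint between the two
#'   distinct covariate values flanking the best split (default);
#'   `"observed"` reports the lower observed value itself. The induced
#'   partition is identical either way.
#' @return One-row tibble of class `ez_maxstat`: `cutpoint`, `max_statistic`
#'   (absolute standardized log-rank statistic), `chisq` (its square),
#'   `p_value`, `n_low`, `n_high`. The full scan is attached as attribute
#'   `"scan"` and is returned by [tidy()].
#' @examples
#' set.seed(1)
#' surv <- tibble::tibble(time = rexp(40, 0.05), event = 1)
#' maxstat_cutpoint(surv, x = rnorm(40))
#' @export
maxstat_cutpoint <- function(surv, x, min_prop = 0.1,
                             p_method = c("bonferroni", "lausen",
                                          "permutation", "none"),
                             n_perm = 1000, seed = NULL,
                             cutpoint_type = c("midpoint", "observed")) {
  p_method <- match.arg(p_method)
  cutpoint_type <- match.arg(cutpoint_type)
  surv <- as_surv_df(surv)
  x <- resolve_covariate(x, surv)
  if (min_prop <= 0 || min_prop >= 0.5) abort("`min_prop` must be in (0, 0.5).")

  scan <- logrank_scan(surv$time, surv$event, x, min_prop, cutpoint_type)
  best <- which.max(abs(scan$statistic))   # ties: lowest cutpoint wins
  b <- abs(scan$statistic[best])

  p <- switch(p_method,
    none = NA_real_,
    bonferroni = p_maxstat_bonferroni(b, nrow(scan)),
    lausen = p_maxstat_lausen(b, min(scan$prop_low), max(scan$prop_low)),
    permutation = with_seed_(seed, {
      exceed <- 0L
      for (i in seq_len(n_perm)) {
        zi <- logrank_scan(surv$time, surv$event, sample(x), min_prop,
                           cutpoint_type)$statistic
        if (max(abs(zi)) >= b - 1e-12) exceed <- exceed + 1L
      }
      (1 + exceed) / (n_perm + 1)
    })
  )

  out <- tibble(cutpoint = scan$cutpoint[best], max_statistic = b,
                chisq = b^2, p_value = p,
                n_low = scan$n_low[best], n_high = scan$n_high[best])
  attr(out, "scan") <- scan
  attr(out, "p_method") <- p_method
  class(out) <- c("ez_maxstat", class(out))
  out
}

#' @method tidy ez_maxstat
#' @export
tidy.ez_maxstat <- function(x, ...) attr(x, "scan")

#' @method glance ez_maxstat
#' @export
glance.ez_maxstat <- function(x, ...) {
  tibble(cutpoint = x$cutpoint, max_statistic = x$max_statistic,
         chisq = x$chisq, p_value = x$p_value,
         n_low = x$n_low, n_high = x$n_high,
         p_method = attr(x, "p_method"))
}
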
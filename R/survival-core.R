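#' Kaplan-Meier product-limit curve
#'
#' Estimates the survival function S(t) by the product-limit method, overall
#' or within groups.
#'
#' @param surv Data frame with columns `time` (months) and `event`
#'   (1 = event observed, 0 = censored); an optional `sample_id` column is
#'   carried through validation.
#' @param group Optional grouping: a vector aligned with the rows of `surv`
#'   or the name of a column in `surv`. One curve is estimated per group.
#' @return A tibble of class `ez_km` with one row per observed time point and
#'   columns `group`, `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#'   S is non-increasing within each group, starts from 1 and only drops at
#'   event times; with no events the curve is constant 1.
#' @examples
#' surv <- tibble::tibble(time = c(5, 10), event = c(1, 0))
#' km_curve(surv)
#' @export
km_curve <- function(surv, group = NULL) {
  surv <- as_surv_df(surv)
  g <- if (is.null(group)) rep("all", nrow(surv)) else {
    if (is.character(group) && length(group) == 1 && group %in% names(surv)) surv[[group]] else group
  }
  if (length(g) != nrow(surv)) abort("`group` must match the survival records.")
  g <- as.character(g)

  curves <- lapply(split(seq_len(nrow(surv)), g), function(idx) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                             data = surv[idx, , drop = FALSE])
    tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
           n_censor = fit$n.censor, survival = fit$surv)
  })
  out <- bind_rows(curves, .id = "group")
  class(out) <- c("ez_km", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square comparing survival between two groups, with
#' the hypergeometric variance at each event time and a 1-df chi-square
#' reference.
#'
#' @inheritParams km_curve
#' @param group Binary labels: a vector aligned with rows of `surv` or a
#'   column name. Both groups must be non-empty and at least one event must
#'   be observed.
#' @return A one-row tibble of class `ez_logrank`: `statistic`, `df`,
#'   `p_value`, `n`, `n_events`.
#' @export
logrank_test <- function(surv, group) {
  surv <- as_surv_df(surv)
  g <- if (is.character(group) && length(group) == 1 && group %in% names(surv)) surv[[group]] else group
  if (length(g) != nrow(surv)) abort("`group` must match the survival records.")
  g <- as.factor(g)
  if (nlevels(droplevels(g)) != 2) abort("`group` must contain exactly two non-empty groups.")
  if (sum(surv$event) == 0) abort("log-rank test needs at least one observed event.")

  d <- data.frame(time = surv$time, event = surv$event, g = droplevels(g))
  fit <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  out <- tibble(statistic = unname(fit$chisq), df = 1L,
                p_value = pchisq(unname(fit$chisq), df = 1, lower.tail = FALSE),
                n = nrow(d), n_events = sum(d$event))
  class(out) <- c("ez_logrank", class(out))
  out
}

#' Univariate Cox proportional-hazards fit
#'
#' Fits a single-covariate Cox model by partial likelihood (Efron tie
#' handling) and reports the log hazard ratio with its Wald test.
#'
#' @inheritParams km_curve
#' @param x Numeric covariate: a vector aligned with rows of `surv` or a
#'   column name. Must take at least two distinct values.
#' @return A one-row tibble of class `ez_cox`: `beta` (log hazard ratio),
#'   `se`, `hazard_ratio` (= exp(beta)), `p_value` (Wald), `n`, `n_events`,
#'   `converged`. Non-convergence (e.g. monotone likelihood under perfect
#'   separation) is flagged, not raised.
#' @export
fit_cox_univariate <- function(surv, x) {
  surv <- as_surv_df(surv)
  x <- resolve_covariate(x, surv)
  if (length(unique(x)) < 2) abort("`x` is constant; the Cox model is undefined.")
  if (sum(surv$event) == 0) abort("Cox fit needs at least one observed event.")

  d <- data.frame(time = surv$time, event = surv$event, x = x)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, data = d, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("converge|infinite|ran out of iterations|beta may be", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(fit$coefficients[1])
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se)) converged <- FALSE
  out <- tibble(beta = beta, se = se, hazard_ratio = exp(beta),
                p_value = 2 * pnorm(-abs(beta / se)),
                n = fit$n, n_events = fit$nevent, converged = converged)
  class(out) <- c("ez_cox", class(out))
  out
}

#' @method tidy ez_cox
#' @export
tidy.ez_cox <- function(x, ...) {
  tibble(term = "x", estimate = x$beta, std.error = x$se,
         statistic = x$beta / x$se, p.value = x$p_value)
}

#' @method glance ez_cox
#' @export
glance.ez_cox <- function(x, ...) {
  tibble(beta = x$beta, hazard_ratio = x$hazard_ratio, p_value = x$p_value,
         n = x$n, n_events = x$n_events, converged = x$converged)
}
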
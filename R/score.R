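# The EZ score: per sample, the sum of the signature genes' Cox
# log-hazard-ratio weights, each signed +1 if the sample's signal exceeds the
# gene's maxstat cutpoint and -1 otherwise. Higher scores mean worse
# prognosis and higher predicted EZH2-inhibitor sensitivity.

#' Compute EZ scores for samples
#'
#' For each sample, score = sum over signature genes of
#' `beta_g * sign_g`, with `sign_g = +1` when the sample's signal for gene g
#' is strictly above that gene's cutpoint and `-1` otherwise. The per-gene
#' signs are retained for audit.
#'
#' @param expr Expression table (wide tibble with `probeset_id` + sample
#'   columns, or matrix with probeset rownames); linear-scale nonnegative
#'   signals. Every signature probeset must be present with no missing
#'   values — there is no imputation, because the signed weighting cannot be
#'   renormalized without changing the score's scale.
#' @param params Score-parameter table (see [ez_signature_params()],
#'   [select_prognostic_genes()]).
#' @return Tibble of class `ez_scores` with columns `sample_id` and `score`.
#'   The samples-by-genes sign matrix is attached as attribute `"signs"`
#'   (see [ez_score_signs()]).
#' @examples
#' params <- ez_signature_params()
#' expr <- matrix(1000, nrow = nrow(params), ncol = 2,
#'                dimnames = list(params$probeset_id, c("a", "b")))
#' compute_ez_score(expr, params)  # every signal above its cutpoint
#' @export
compute_ez_score <- function(expr, params) {
  validate_score_params(params, tol = 1e-6)
  m <- as_expr_matrix(expr)
  missing <- setdiff(params$probeset_id, rownames(m))
  if (length(missing)) {
    abort(paste("signature probeset(s) absent from the expression data:",
                paste(missing, collapse = ", ")))
  }
  sig <- m[params$probeset_id, , drop = FALSE]
  if (anyNA(sig)) abort("missing values on signature probesets; the score is undefined.")
  if (any(sig < 0)) abort("expression signals must be nonnegative (linear scale).")

  signs <- ifelse(sig > params$cutpoint, 1, -1)   # cutpoints recycle down rows
  score <- colSums(signs * params$beta)
  out <- tibble(sample_id = colnames(m), score = unname(score))
  attr(out, "signs") <- t(signs)
  attr(out, "params") <- params
  class(out) <- c("ez_scores", class(out))
  out
}

#' Per-gene sign matrix of computed scores
#'
#' @param scores Result of [compute_ez_score()].
#' @return Samples-by-genes matrix of +1/-1 signs.
#' @export
ez_score_signs <- function(scores) {
  s <- attr(scores, "signs")
  if (is.null(s)) abort("`scores` carries no sign matrix; use compute_ez_score().")
  s
}

#' Stratify samples by score
#'
#' Labels each sample `high` when its score strictly exceeds the threshold
#' and `low` otherwise. The threshold is either a fixed value or
#' `"maxstat"`, in which case it is discovered by running
#' [maxstat_cutpoint()] on the score against survival.
#'
#' @param scores Tibble with `sample_id` and `score` (e.g. from
#'   [compute_ez_score()]).
#' @param threshold Numeric threshold, or `"maxstat"` (default) to discover
#'   it from `surv`.
#' @param surv Survival table, required when `threshold = "maxstat"`; matched
#'   to `scores` by `sample_id`.
#' @param min_prop Admissibility bound for the maxstat scan.
#' @return `scores` with an added `risk_group` factor (`low`, `high`);
#'   attributes `"threshold"` and (when discovered) `"maxstat"` record how
#'   the split was made.
#' @export
stratify_scores <- function(scores, threshold = "maxstat", surv = NULL,
                            min_prop = 0.1) {
  if (!is.data.frame(scores) || !all(c("sample_id", "score") %in% names(scores))) {
    abort("`scores` must have columns `sample_id` and `score`.")
  }
  ms <- NULL
  if (identical(threshold, "maxstat")) {
    if (is.null(surv)) abort("`surv` is required when threshold = \"maxstat\".")
    surv <- as_surv_df(surv)
    idx <- match(surv$sample_id, scores$sample_id)
    if (anyNA(idx)) abort("every survival record needs a matching score.")
    ms <- maxstat_cutpoint(surv, scores$score[idx], min_prop = min_prop)
    threshold <- ms$cutpoint
  }
  if (!is.numeric(threshold) || length(threshold) != 1) {
    abort("`threshold` must be a single number or \"maxstat\".")
  }
  out <- scores |>
    mutate(risk_group = factor(ifelse(.data$score > threshold, "high", "low"),
                               levels = c("low", "high")))
  attr(out, "threshold") <- threshold
  attr(out, "maxstat") <- ms
  attr(out, "signs") <- attr(scores, "signs")
  class(out) <- unique(c("ez_scores", class(out)))
  out
}

#' Associate scores with survival
#'
#' Two complementary views of the score's prognostic value: a continuous
#' univariate Cox fit on the score, and a two-group comparison
#' (Kaplan-Meier curves + log-rank test) after stratification.
#'
#' @param scores Tibble with `sample_id`, `score`, and optionally a
#'   `risk_group` from [stratify_scores()]; without one, stratification is
#'   performed here using `threshold`.
#' @param surv Survival table matched by `sample_id`.
#' @param threshold Passed to [stratify_scores()] when `scores` is not yet
#'   stratified (default `"maxstat"`).
#' @param min_prop Admissibility bound for maxstat-based stratification.
#' @return List of class `ez_surv_assoc`: `cox` (continuous fit), `logrank`,
#'   `km` (curves by risk group), `scores` (stratified), `threshold`.
#'   [glance()] condenses it to one row.
#' @export
score_survival_association <- function(scores, surv, threshold = "maxstat",
                                       min_prop = 0.1) {
  surv <- as_surv_df(surv)
  if (!"risk_group" %in% names(scores)) {
    scores <- stratify_scores(scores, threshold, surv, min_prop)
  }
  idx <- match(surv$sample_id, scores$sample_id)
  if (anyNA(idx)) abort("every survival record needs a matching score.")
  sc <- scores$score[idx]
  grp <- scores$risk_group[idx]

  cox <- fit_cox_univariate(surv, sc)
  lr <- logrank_test(surv, as.character(grp))
  km <- km_curve(surv, as.character(grp))

  out <- list(cox = cox, logrank = lr, km = km, scores = scores,
              threshold = attr(scores, "threshold"))
  class(out) <- "ez_surv_assoc"
  out
}

#' @method glance ez_surv_assoc
#' @export
glance.ez_surv_assoc <- function(x, ...) {
  tibble(beta = x$cox$beta, hazard_ratio = x$cox$hazard_ratio,
         cox_p = x$cox$p_value, logrank_p = x$logrank$p_value,
         threshold = x$threshold %||% NA_real_,
         n_high = sum(x$scores$risk_group == "high"),
         n_low = sum(x$scores$risk_group == "low"))
}

#' @export
print.ez_surv_assoc <- function(x, ...) {
  cat("EZ score vs survival\n")
  cat(sprintf("  continuous Cox: beta = %.3f (HR %.2f), p = %.3g\n",
              x$cox$beta, x$cox$hazard_ratio, x$cox$p_value))
  cat(sprintf("  stratified at %.3f: %d high / %d low, log-rank p = %.3g\n",
              x$threshold %||% NA_real_,
              sum(x$scores$risk_group == "high"),
              sum(x$scores$risk_group == "low"), x$logrank$p_value))
  invisible(x)
}

#' Correlate scores with drug sensitivity
#'
#' Correlation between the score and a per-sample viability metric (e.g.
#' percent viable malignant plasma cells under 1 uM EPZ-6438 at day 8,
#' relative to control). A negative correlation means higher-score samples
#' lose more viability, i.e. respond better to the drug.
#'
#' @param scores Tibble with `sample_id` and `score`.
#' @param sensitivity Tibble with `sample_id` and `viability`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return One-row tibble: `r`, `p_value`, `n`, `method`.
#' @export
score_sensitivity_correlation <- function(scores, sensitivity,
                                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!all(c("sample_id", "viability") %in% names(sensitivity))) {
    abort("`sensitivity` must have columns `sample_id` and `viability`.")
  }
  d <- inner_join(as_tibble(scores)[c("sample_id", "score")],
                  as_tibble(sensitivity)[c("sample_id", "viability")],
                  by = "sample_id")
  if (nrow(d) < 3) abort("need at least 3 paired score/viability records.")
  if (sd(d$score) == 0 || sd(d$viability) == 0) {
    abort("scores and viability must each be non-constant.")
  }
  ct <- suppressWarnings(cor.test(d$score, d$viability, method = method))
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(d),
         method = method)
}
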
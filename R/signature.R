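# Signature construction: from a differential-expression table and an
# epigenetic-mark gene list to a per-gene score-parameter table
# (cutpoint, Cox beta, hazard ratio, prognostic direction).

#' Filter a differential-expression table
#'
#' Retains upregulated genes passing a fold-change and an adjusted-p
#' threshold (`fold_change >= fc_min` and `padj < fdr_max`). Only the
#' upregulated direction is considered: fold changes are treated/control
#' ratios on the linear scale.
#'
#' @param de Data frame with columns `fold_change` (> 0, linear scale) and
#'   `padj` (adjusted p in \[0,1\]); identifier columns (e.g. `gene`,
#'   `probeset`) are carried through.
#' @param fc_min Minimum fold change (default 2).
#' @param fdr_max Strict upper bound on the adjusted p (default 0.05).
#' @return The filtered tibble (possibly empty).
#' @export
filter_de_genes <- function(de, fc_min = 2, fdr_max = 0.05) {
  if (!is.data.frame(de) || !all(c("fold_change", "padj") %in% names(de))) {
    abort("`de` must have columns `fold_change` and `padj`.")
  }
  if (fc_min <= 0 || fdr_max <= 0) abort("thresholds must be positive.")
  if (any(de$fold_change <= 0, na.rm = TRUE)) abort("`fold_change` must be positive.")
  as_tibble(de) |>
    filter(.data$fold_change >= fc_min, .data$padj < fdr_max)
}

#' Intersect a gene set with an epigenetic-mark gene set
#'
#' Exact set intersection on normalized identifiers: gene symbols are matched
#' case-insensitively, probeset ids (ending in `_at`) verbatim. The returned
#' identifiers keep the casing of the first argument.
#'
#' @param genes,mark_genes Character vectors of identifiers (or data frames
#'   whose first column holds them).
#' @return Character vector, the intersection without duplicates.
#' @export
intersect_epigenetic <- function(genes, mark_genes) {
  genes <- as_gene_set(genes, "genes")
  mark_genes <- as_gene_set(mark_genes, "mark_genes")
  genes[normalize_ids(genes) %in% normalize_ids(mark_genes)]
}

#' Select prognostic genes and estimate their score parameters
#'
#' For each candidate probeset: discover the expression cutpoint by
#' [maxstat_cutpoint()], dichotomize the signal at it, fit a univariate Cox
#' model on the above-cutpoint indicator, and retain genes whose selection
#' p-value falls below `alpha`. Retained rows carry everything needed to
#' score new samples: cutpoint, beta (log hazard ratio of the indicator),
#' hazard ratio, maxstat chi-square, p-values and the prognostic direction
#' (`Bad` if hazard ratio > 1, else `Good`).
#'
#' @param expr Expression table: wide tibble with a `probeset_id` column and
#'   one column per sample (linear-scale, nonnegative signals), or a numeric
#'   matrix with probesets as rownames.
#' @param surv Survival table matching the expression columns by `sample_id`
#'   (column order is used when ids are absent).
#' @param candidates Candidate probesets: character vector, or a data frame
#'   with `probeset_id` and optionally `gene_symbol`.
#' @param alpha Per-gene selection level (default 0.05).
#' @param min_prop Admissibility bound passed to [maxstat_cutpoint()].
#' @param p_source Selection p-value: `"maxstat"` (multiplicity-corrected
#'   maxstat p, default) or `"cox"` (Wald p of the dichotomized fit).
#' @param p_adjust Optional multiple-testing correction across candidates
#'   applied to the selection p before thresholding (any [p.adjust()] method;
#'   default `"none"`).
#' @param dichotomize If `FALSE`, the Cox model uses the continuous signal
#'   instead of the above-cutpoint indicator (the cutpoint is still reported).
#' @return Tibble of class `ez_score_params`, one row per retained gene:
#'   `probeset_id`, `gene_symbol`, `cutpoint`, `beta`, `hazard_ratio`,
#'   `chisq`, `p_value`, `p_maxstat`, `p_cox`, `prognostic`, `converged`.
#' @export
select_prognostic_genes <- function(expr, surv, candidates, alpha = 0.05,
                                    min_prop = 0.1,
                                    p_source = c("maxstat", "cox"),
                                    p_adjust = "none", dichotomize = TRUE) {
  p_source <- match.arg(p_source)
  m <- as_expr_matrix(expr)
  surv <- as_surv_df(surv)
  if (ncol(m) != nrow(surv)) abort("expression columns and survival records must match.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")

  if (is.data.frame(candidates)) {
    ids <- as.character(candidates$probeset_id %||% candidates[[1]])
    syms <- as.character(candidates$gene_symbol %||% ids)
  } else {
    ids <- as.character(candidates)
    syms <- ids
  }
  if (length(ids) == 0) return(empty_score_params())

  present <- ids %in% rownames(m)
  if (any(!present)) {
    warn(sprintf("%d candidate probeset(s) absent from the matrix, skipped: %s",
                 sum(!present), paste(head(ids[!present], 5), collapse = ", ")))
  }

  rows <- map_dfr(which(present), function(i) {
    sig <- m[ids[i], ]
    ms <- tryCatch(maxstat_cutpoint(surv, sig, min_prop = min_prop),
                   error = function(e) NULL)
    if (is.null(ms)) return(NULL)
    z <- if (dichotomize) as.numeric(sig > ms$cutpoint) else sig
    cox <- fit_cox_univariate(surv, z)
    tibble(probeset_id = ids[i], gene_symbol = syms[i],
           cutpoint = ms$cutpoint, beta = cox$beta,
           hazard_ratio = cox$hazard_ratio, chisq = ms$chisq,
           p_maxstat = ms$p_value, p_cox = cox$p_value,
           converged = cox$converged)
  })
  if (nrow(rows) == 0) return(empty_score_params())

  rows$p_value <- p.adjust(if (p_source == "maxstat") rows$p_maxstat else rows$p_cox,
                           method = p_adjust)
  out <- rows |>
    filter(.data$p_value < alpha, .data$converged) |>
    mutate(prognostic = ifelse(.data$hazard_ratio > 1, "Bad", "Good")) |>
    select("probeset_id", "gene_symbol", "cutpoint", "beta", "hazard_ratio",
           "chisq", "p_value", "p_maxstat", "p_cox", "prognostic", "converged")
  class(out) <- c("ez_score_params", class(out))
  out
}

empty_score_params <- function() {
  out <- tibble(probeset_id = character(), gene_symbol = character(),
                cutpoint = double(), beta = double(), hazard_ratio = double(),
                chisq = double(), p_value = double(), p_maxstat = double(),
                p_cox = double(), prognostic = character(), converged = logical())
  class(out) <- c("ez_score_params", class(out))
  out
}

#' Validate a score-parameter table
#'
#' Checks the structural invariants a score-parameter table must satisfy
#' before it can be used to score samples: required columns, unique probeset
#' ids, positive hazard ratios, `beta = log(hazard_ratio)` to tolerance, and
#' the prognostic label `Bad` exactly when the hazard ratio exceeds 1.
#'
#' @param params A score-parameter table (e.g. from
#'   [select_prognostic_genes()] or [ez_signature_params()]).
#' @param tol Tolerance on `|beta - log(hazard_ratio)|` (default 1e-8).
#' @return `params`, invisibly; errors describe the first violated invariant.
#' @export
validate_score_params <- function(params, tol = 1e-8) {
  need <- c("probeset_id", "gene_symbol", "cutpoint", "beta", "hazard_ratio",
            "p_value", "prognostic")
  miss <- setdiff(need, names(params))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(params) == 0) return(invisible(params))
  if (anyDuplicated(params$probeset_id)) abort("duplicate probeset ids.")
  if (any(params$hazard_ratio <= 0)) abort("hazard ratios must be positive.")
  if (any(abs(params$beta - log(params$hazard_ratio)) > tol)) {
    abort("beta and log(hazard_ratio) disagree beyond tolerance.")
  }
  if (!all(params$prognostic %in% c("Good", "Bad"))) {
    abort("prognostic labels must be 'Good' or 'Bad'.")
  }
  if (any((params$hazard_ratio > 1) != (params$prognostic == "Bad"))) {
    abort("prognostic must be 'Bad' exactly when hazard_ratio > 1.")
  }
  invisible(params)
}
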
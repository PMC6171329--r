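# Readers and writers for the pipeline's plain-text formats, the shipped
# 15-gene signature fixture, and the qPCR relative-expression utility.

# Wide expression tibble (probeset_id + sample columns) or matrix -> matrix.
as_expr_matrix <- function(expr) {
  if (is.matrix(expr)) {
    if (is.null(rownames(expr)) || is.null(colnames(expr))) {
      abort("expression matrices need probeset rownames and sample colnames.")
    }
    return(expr)
  }
  if (!is.data.frame(expr)) abort("`expr` must be a data frame or matrix.")
  idcol <- intersect(c("probeset_id", "gene", "gene_symbol"), names(expr))[1]
  if (is.na(idcol)) abort("`expr` needs a `probeset_id` identifier column.")
  m <- as.matrix(expr[setdiff(names(expr), idcol)])
  rownames(m) <- as.character(expr[[idcol]])
  if (!is.numeric(m)) abort("expression signals must be numeric.")
  if (anyDuplicated(rownames(m))) abort("duplicate probeset ids.")
  if (anyDuplicated(colnames(m))) abort("duplicate sample ids.")
  m
}

#' Read an expression matrix
#'
#' Tab-delimited text: first column probeset ids, header row of sample ids,
#' linear-scale nonnegative signals.
#'
#' @param path File path.
#' @return Wide tibble with `probeset_id` + one column per sample.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[1] <- "probeset_id"
  m <- as_expr_matrix(x)   # id/uniqueness/numeric checks
  if (any(m < 0, na.rm = TRUE)) abort("negative expression signals are not allowed.")
  x
}

#' Write an expression matrix
#'
#' @param expr Wide tibble or matrix (see [read_expression()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  m <- as_expr_matrix(expr)
  out <- cbind(tibble(probeset_id = rownames(m)), as.data.frame(m))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a survival table
#'
#' CSV with columns `sample_id`, `time` (months), `event` (0/1).
#'
#' @param path File path.
#' @return Validated tibble: `sample_id`, `time`, `event`.
#' @export
read_survival <- function(path) {
  as_surv_df(readr::read_csv(path, show_col_types = FALSE))
}

#' Read a gene set (one identifier per line)
#'
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return Character vector without duplicates.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readr::read_lines(path))
  as_gene_set(x[nzchar(x) & !startsWith(x, "#")])
}

#' Read gene sets in GMT format
#'
#' Tab-separated: set name, description, then member identifiers.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) as_gene_set(p[-(1:2)])),
           vapply(parts, `[[`, "", 1))
}

#' The published 15-gene EZ-score parameter table
#'
#' Loads the shipped signature fixture: for each of the 15
#' EZH2-inhibitor-deregulated, H3K27me3-associated prognostic genes, its
#' probeset, maxstat cutpoint (linear MAS5 scale), chi-square, p-value,
#' hazard ratio and prognostic direction (12 Good / 3 Bad). The Cox weight
#' `beta` is reconstructed as `log(hazard_ratio)` since betas are not
#' printed; the two-significant-figure rounding of the hazard ratios
#' propagates about 1% uncertainty into scores.
#'
#' @return Tibble of class `ez_score_params` (15 rows), validated.
#' @examples
#' params <- ez_signature_params()
#' table(params$prognostic)
#' @export
ez_signature_params <- function() {
  path <- system.file("extdata", "ez_signature_genes.csv", package = "ezscore",
                      mustWork = TRUE)
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = "ccdddcc")
  x <- x |>
    mutate(cutpoint = as.numeric(.data$cutpoint),
           chisq = as.numeric(.data$chisq),
           p_value = as.numeric(.data$p_value),
           hazard_ratio = as.numeric(.data$hazard_ratio),
           beta = log(as.numeric(.data$hazard_ratio))) |>
    select("probeset_id", "gene_symbol", "cutpoint", "beta", "hazard_ratio",
           "chisq", "p_value", "prognostic")
  class(x) <- c("ez_score_params", class(x))
  validate_score_params(x)
}

#' Write / read score-parameter tables
#'
#' CSV round-trip for score-parameter tables in the fixture schema.
#'
#' @param params Score-parameter table.
#' @param path File path.
#' @return `path` invisibly (write); validated tibble (read).
#' @export
write_score_params <- function(params, path) {
  validate_score_params(params, tol = 1e-6)
  readr::write_csv(params, path)
  invisible(path)
}

#' @rdname write_score_params
#' @export
read_score_params <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!"beta" %in% names(x)) x$beta <- log(x$hazard_ratio)
  class(x) <- c("ez_score_params", class(x))
  validate_score_params(x, tol = 1e-6)
}

#' Relative qPCR expression (percent of positive control)
#'
#' Delta-Ct of the gene of interest against the reference gene, compared to
#' a positive control: `dCt = ct_gene - ct_ref`,
#' `ddCt = dCt - dct_positive_control`, result `100 / 2^ddCt`.
#'
#' @param ct_gene,ct_ref Threshold cycles for the gene of interest and the
#'   reference gene (vectorized).
#' @param dct_positive_control Delta-Ct of the positive control.
#' @return Percent expression relative to the positive control.
#' @examples
#' relative_qpcr_expression(25, 20, 5)   # ddCt = 0 -> 100
#' relative_qpcr_expression(26, 20, 5)   # ddCt = 1 -> 50
#' @export
relative_qpcr_expression <- function(ct_gene, ct_ref, dct_positive_control) {
  if (!all(is.finite(ct_gene), is.finite(ct_ref), is.finite(dct_positive_control))) {
    abort("Ct values must be finite.")
  }
  ddct <- (ct_gene - ct_ref) - dct_positive_control
  100 / 2^ddct
}
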
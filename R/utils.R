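# Internal validation and coercion helpers shared across modules.

# Coerce and validate a survival table: columns time (months, >= 0) and
# event (0/1), optional sample_id (unique). Returns a tibble with all three.
as_surv_df <- function(surv, arg = "surv") {
  if (!is.data.frame(surv)) {
    abort(sprintf("`%s` must be a data frame with columns time and event.", arg))
  }
  if (!all(c("time", "event") %in% names(surv))) {
    abort(sprintf("`%s` must have columns `time` and `event`.", arg))
  }
  if (nrow(surv) == 0) abort(sprintf("`%s` has no records.", arg))
  out <- as_tibble(surv)
  if (!"sample_id" %in% names(out)) {
    out$sample_id <- sprintf("s%03d", seq_len(nrow(out)))
  }
  out$sample_id <- as.character(out$sample_id)
  if (anyDuplicated(out$sample_id)) abort("sample_id values must be unique.")
  if (!is.numeric(out$time) || anyNA(out$time) || any(out$time < 0)) {
    abort("`time` must be nonnegative and non-missing.")
  }
  ev <- out$event
  if (anyNA(ev) || !all(ev %in% c(0, 1))) {
    abort("`event` must be 0 (censored) or 1 (event observed).")
  }
  out$event <- as.integer(ev)
  out[c("sample_id", "time", "event")]
}

# Resolve a per-sample covariate given either a numeric vector aligned with
# the survival rows or the (string) name of a column in `data`.
resolve_covariate <- function(x, data, arg = "x") {
  if (is.character(x) && length(x) == 1 && x %in% names(data)) {
    x <- data[[x]]
  }
  if (!is.numeric(x)) abort(sprintf("`%s` must be numeric (or name a numeric column).", arg))
  if (length(x) != nrow(data)) {
    abort(sprintf("`%s` has length %d but there are %d survival records.",
                  arg, length(x), nrow(data)))
  }
  if (anyNA(x)) abort(sprintf("`%s` contains missing values.", arg))
  as.numeric(x)
}

# Case-insensitive gene-identifier normalization. Probeset ids (contain "_at")
# are matched verbatim; symbols are upper-cased.
normalize_ids <- function(ids) {
  ids <- as.character(ids)
  ifelse(grepl("_at$", ids), ids, toupper(ids))
}

# Gene sets are character vectors; also accept a data frame whose first
# column holds the identifiers.
as_gene_set <- function(x, arg = "gene set") {
  if (is.data.frame(x)) x <- x[[1]]
  if (is.factor(x)) x <- as.character(x)
  if (!is.character(x)) abort(sprintf("`%s` must be a character vector of identifiers.", arg))
  unique(x[!is.na(x) & nzchar(x)])
}

# Run an expression with a temporary RNG state when `seed` is given.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}
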
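# Epigenetic set logic and promoter-methylation analyses: overlap of
# drug-deregulated genes with histone-mark gene sets, promoter CpG
# methylation calls from beta values, and the sensitive-vs-resistant
# methylation comparison.

#' Overlap of deregulated genes with histone-mark gene sets
#'
#' Sizes of every Venn region among a deregulated gene set, an H3K27me3 set,
#' and an H3K4me3 set, plus the field's summary counts: genes carrying the
#' repressive mark, and bivalent genes (both marks) among the deregulated
#' set. Identifiers are normalized as in [intersect_epigenetic()].
#'
#' @param de,k27,k4 Character vectors of identifiers (or data frames whose
#'   first column holds them).
#' @return One-row tibble with exclusive region sizes (`de_only`, `k27_only`,
#'   `k4_only`, `de_k27_only`, `de_k4_only`, `k27_k4_only`, `de_k27_k4`),
#'   the inclusive overlaps `de_k27`, `de_k4`, `k27_k4`, the bivalent count
#'   within the deregulated set (`de_bivalent`, equal to `de_k27_k4`), and
#'   `union_size`.
#' @export
mark_overlap_counts <- function(de, k27, k4) {
  de <- unique(normalize_ids(as_gene_set(de, "de")))
  k27 <- unique(normalize_ids(as_gene_set(k27, "k27")))
  k4 <- unique(normalize_ids(as_gene_set(k4, "k4")))
  u <- union(union(de, k27), k4)
  in_de <- u %in% de; in_27 <- u %in% k27; in_4 <- u %in% k4
  tibble(
    de_only = sum(in_de & !in_27 & !in_4),
    k27_only = sum(!in_de & in_27 & !in_4),
    k4_only = sum(!in_de & !in_27 & in_4),
    de_k27_only = sum(in_de & in_27 & !in_4),
    de_k4_only = sum(in_de & !in_27 & in_4),
    k27_k4_only = sum(!in_de & in_27 & in_4),
    de_k27_k4 = sum(in_de & in_27 & in_4),
    de_k27 = sum(in_de & in_27),
    de_k4 = sum(in_de & in_4),
    k27_k4 = sum(in_27 & in_4),
    de_bivalent = sum(in_de & in_27 & in_4),
    union_size = length(u)
  )
}

#' Classify promoter methylation per gene and sample
#'
#' A gene-sample pair is called methylated when at least one CpG overlapping
#' the gene's promoter interval has beta strictly above `beta_threshold`.
#' Coordinates are 0-based half-open (BED convention): a CpG at position p
#' overlaps \[start, end) iff start <= p < end. Genes with no overlapping
#' CpG get status `"no-data"` and are excluded from downstream tests.
#'
#' @param meth Beta-value table: wide tibble with `cpg_id` + one column per
#'   sample, betas in \[0,1\].
#' @param cpg_coords Tibble `cpg_id`, `chrom`, `pos` (0-based).
#' @param promoters Tibble `gene_symbol`, `chrom`, `start`, `end`
#'   (0-based half-open, start < end, one interval per gene).
#' @param beta_threshold Strict lower bound for a "highly methylated" CpG
#'   (default 0.8).
#' @return Long tibble: `gene_symbol`, `sample_id`, `n_cpg` (CpGs overlapping
#'   the promoter), `status` in `methylated` / `unmethylated` / `no-data`.
#' @export
classify_promoter_methylation <- function(meth, cpg_coords, promoters,
                                          beta_threshold = 0.8) {
  if (beta_threshold <= 0 || beta_threshold >= 1) {
    abort("`beta_threshold` must be in (0, 1).")
  }
  if (!"cpg_id" %in% names(meth)) abort("`meth` must have a `cpg_id` column.")
  if (!all(c("cpg_id", "chrom", "pos") %in% names(cpg_coords))) {
    abort("`cpg_coords` must have columns cpg_id, chrom, pos.")
  }
  if (!all(c("gene_symbol", "chrom", "start", "end") %in% names(promoters))) {
    abort("`promoters` must have columns gene_symbol, chrom, start, end.")
  }
  if (any(promoters$start >= promoters$end)) abort("promoter start must be < end.")
  if (anyDuplicated(promoters$gene_symbol)) abort("one promoter interval per gene.")

  b <- as.matrix(meth[setdiff(names(meth), "cpg_id")])
  rownames(b) <- meth$cpg_id
  if (anyNA(b) || any(b < 0 | b > 1)) abort("beta values must lie in [0, 1].")
  samples <- colnames(b)

  # map each CpG to the promoters it falls in (0-based half-open on both
  # sides; IRanges is 1-based closed, so [start, end) becomes [start+1, end])
  co <- cpg_coords[cpg_coords$cpg_id %in% rownames(b), ]
  hits <- map_dfr(split(seq_len(nrow(promoters)), promoters$chrom), function(pi) {
    ci <- which(co$chrom == promoters$chrom[pi[1]])
    if (length(ci) == 0) return(NULL)
    q <- IRanges::IRanges(start = co$pos[ci] + 1, width = 1)
    s <- IRanges::IRanges(start = promoters$start[pi] + 1, end = promoters$end[pi])
    ov <- IRanges::findOverlaps(q, s)
    tibble(cpg_id = co$cpg_id[ci][S4Vectors::queryHits(ov)],
           gene_symbol = promoters$gene_symbol[pi][S4Vectors::subjectHits(ov)])
  })

  genes <- promoters$gene_symbol
  n_cpg <- setNames(integer(length(genes)), genes)
  call_mat <- matrix(NA, nrow = length(genes), ncol = length(samples),
                     dimnames = list(genes, samples))
  if (nrow(hits) > 0) {
    tab <- table(hits$gene_symbol)
    n_cpg[names(tab)] <- as.integer(tab)
    # any-CpG rule: a gene-sample pair is methylated iff any promoter CpG
    # exceeds the threshold
    agg <- rowsum((b[hits$cpg_id, , drop = FALSE] > beta_threshold) + 0,
                  group = hits$gene_symbol)
    call_mat[rownames(agg), ] <- agg > 0
  }
  per_gene <- tibble(
    gene_symbol = rep(genes, times = length(samples)),
    sample_id = rep(samples, each = length(genes)),
    n_cpg = rep(unname(n_cpg), times = length(samples)),
    status = ifelse(is.na(c(call_mat)), "no-data",
                    ifelse(c(call_mat) == 1, "methylated", "unmethylated"))
  )
  per_gene$status <- factor(per_gene$status,
                            levels = c("methylated", "unmethylated", "no-data"))
  per_gene
}

#' Derive promoter intervals from transcription start sites
#'
#' Builds a promoter map (one interval per gene, 0-based half-open) from a
#' TSS annotation using a fixed window, by default 1500 bp upstream to
#' 500 bp downstream — a common convention for 450k promoter analyses. For
#' genes annotated with several TSS rows, the first is used.
#'
#' @param annotation Tibble with `gene_symbol`, `chrom`, `tss` (0-based
#'   position) and `strand` (`"+"`/`"-"`).
#' @param upstream,downstream Window extent in bp relative to the TSS,
#'   oriented by strand.
#' @return Tibble `gene_symbol`, `chrom`, `start`, `end` suitable for
#'   [classify_promoter_methylation()].
#' @export
promoters_from_tss <- function(annotation, upstream = 1500, downstream = 500) {
  need <- c("gene_symbol", "chrom", "tss", "strand")
  if (!all(need %in% names(annotation))) {
    abort("`annotation` must have columns gene_symbol, chrom, tss, strand.")
  }
  if (!all(annotation$strand %in% c("+", "-"))) abort("strand must be '+' or '-'.")
  ann <- as_tibble(annotation) |> distinct(.data$gene_symbol, .keep_all = TRUE)
  fwd <- ann$strand == "+"
  start <- ifelse(fwd, ann$tss - upstream, ann$tss - downstream + 1)
  end <- ifelse(fwd, ann$tss + downstream, ann$tss + upstream + 1)
  tibble(gene_symbol = ann$gene_symbol, chrom = ann$chrom,
         start = pmax(0, as.integer(start)), end = as.integer(end))
}

#' Compare promoter methylation between sensitive and resistant lines
#'
#' Summarizes each sample by the fraction of target genes (with promoter CpG
#' data) called methylated, and compares the two groups with a two-sided
#' Wilcoxon rank-sum test. A per-gene 2x2 count table (methylated or not, by
#' group) is also returned.
#'
#' @param status Output of [classify_promoter_methylation()].
#' @param groups Tibble `sample_id`, `group` with exactly two non-empty
#'   groups (e.g. sensitive / resistant).
#' @param target_genes Optional gene set restricting the analysis.
#' @return List of class `ez_meth_cmp`: `p_value`, `statistic` (rank-sum W),
#'   `per_sample` (sample, group, n_genes, fraction_methylated), `per_gene`
#'   (gene by group methylated/total counts).
#' @export
compare_methylation_by_sensitivity <- function(status, groups,
                                               target_genes = NULL) {
  if (!all(c("sample_id", "group") %in% names(groups))) {
    abort("`groups` must have columns `sample_id` and `group`.")
  }
  groups <- as_tibble(groups)
  groups$group <- droplevels(as.factor(groups$group))
  if (nlevels(groups$group) != 2) abort("exactly two non-empty groups are required.")

  st <- as_tibble(status) |> filter(.data$status != "no-data")
  if (!is.null(target_genes)) {
    tg <- normalize_ids(as_gene_set(target_genes, "target_genes"))
    st <- st |> filter(normalize_ids(.data$gene_symbol) %in% tg)
  }
  if (nrow(st) == 0) abort("no gene-sample pairs with methylation data.")

  per_sample <- st |>
    group_by(.data$sample_id) |>
    summarise(n_genes = n(),
              fraction_methylated = mean(.data$status == "methylated"),
              .groups = "drop") |>
    inner_join(groups, by = "sample_id")
  if (nlevels(droplevels(per_sample$group)) != 2) {
    abort("both groups need at least one sample with methylation data.")
  }

  lv <- levels(per_sample$group)
  a <- per_sample$fraction_methylated[per_sample$group == lv[1]]
  bvals <- per_sample$fraction_methylated[per_sample$group == lv[2]]
  if (sd(per_sample$fraction_methylated) == 0) {
    # no variation at all: the rank-sum z-score is 0/0; report no difference
    wt <- list(p.value = 1, statistic = length(a) * length(bvals) / 2,
               method = "Wilcoxon rank sum test (degenerate: no variation)")
  } else {
    wt <- suppressWarnings(wilcox.test(a, bvals, alternative = "two.sided"))
  }

  per_gene <- st |>
    inner_join(groups, by = "sample_id") |>
    group_by(.data$gene_symbol, .data$group) |>
    summarise(n_methylated = sum(.data$status == "methylated"),
              n_total = n(), .groups = "drop")

  out <- list(p_value = wt$p.value, statistic = unname(wt$statistic),
              method = wt$method, per_sample = per_sample, per_gene = per_gene)
  class(out) <- "ez_meth_cmp"
  out
}

#' @method glance ez_meth_cmp
#' @export
glance.ez_meth_cmp <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         n_samples = nrow(x$per_sample))
}

#' Overlap of promoter-methylated genes with drug-deregulated genes
#'
#' Nested intersection counts: how many deregulated genes carry promoter
#' methylation, and how many of those are additionally reactivated by a
#' demethylating agent (per a provided DE table filtered at
#' `fold_change >= fc_min` with no adjusted-p restriction).
#'
#' @param methylated_genes Gene set with promoter methylation calls.
#' @param de_upregulated Drug-upregulated gene set.
#' @param decitabine_de Optional DE table (columns as in
#'   [filter_de_genes()]) for the demethylating-agent reactivation filter.
#' @param fc_min Fold-change threshold for that filter (default 1.5).
#' @return One-row tibble: `n_methylated`, `n_de`, `n_meth_de`, and (when a
#'   table is supplied) `n_meth_de_reactivated`.
#' @export
methylation_de_overlap <- function(methylated_genes, de_upregulated,
                                   decitabine_de = NULL, fc_min = 1.5) {
  mg <- unique(normalize_ids(as_gene_set(methylated_genes, "methylated_genes")))
  de <- unique(normalize_ids(as_gene_set(de_upregulated, "de_upregulated")))
  meth_de <- intersect(mg, de)
  out <- tibble(n_methylated = length(mg), n_de = length(de),
                n_meth_de = length(meth_de),
                n_meth_de_reactivated = NA_integer_)
  if (!is.null(decitabine_de)) {
    react <- filter_de_genes(decitabine_de, fc_min = fc_min, fdr_max = 1)
    rg <- normalize_ids(as_gene_set(react, "decitabine_de"))
    out$n_meth_de_reactivated <- length(intersect(meth_de, rg))
  }
  out
}
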
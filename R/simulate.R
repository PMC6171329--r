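# Seeded generators reproducing the statistical structure the score analysis
# assumes: log-normal linear-scale expression with planted dichotomous
# prognostic effects, right-censored exponential survival whose hazard is
# multiplied by exp(beta) above each planted cutpoint, drug response linearly
# coupled to the true score, and bimodal promoter methylation with a
# resistant-line shift. All ground truth is recorded for recovery tests.

#' Generate a synthetic expression + survival cohort
#'
#' Expression signals are log-normal on the linear scale (MAS5-like,
#' nonnegative). For each planted gene, the above-cutpoint indicator
#' multiplies the sample's hazard by `exp(beta)`; survival times are
#' exponential with that hazard, and independent uniform administrative
#' censoring is calibrated to a target censored fraction. The truth —
#' planted cutpoints and betas, the true signed score per sample, and the
#' seed — is returned alongside the data.
#'
#' @param n_samples Number of samples (>= 10).
#' @param n_genes Number of genes; ids are `gene_001`, ...
#' @param planted Optional tibble of planted effects: `gene` (id or index),
#'   `beta` (log hazard ratio of the above-cutpoint indicator), and
#'   optionally `cutpoint_quantile` (where on that gene's signal
#'   distribution the cutpoint sits; default 0.5).
#' @param censoring Target censored fraction in \[0, 1); 0 disables
#'   censoring. An unattainable target raises an error.
#' @param baseline_hazard Exponential baseline hazard (per month).
#' @param meanlog,sdlog Log-normal expression parameters (recycled per gene).
#' @param seed RNG seed; identical seeds give identical cohorts.
#' @return List of class `ez_cohort`: `expr` (wide tibble, `probeset_id` +
#'   sample columns), `surv` (sample_id, time, event), `truth` (list:
#'   `planted` with realized cutpoints, `baseline_hazard`,
#'   `censoring_target`, `true_score` per sample, `seed`).
#' @export
generate_cohort <- function(n_samples = 200, n_genes = 50, planted = NULL,
                            censoring = 0.3, baseline_hazard = 0.02,
                            meanlog = 5, sdlog = 1, seed = NULL) {
  if (n_samples < 10) abort("`n_samples` must be at least 10.")
  if (censoring < 0 || censoring >= 1) abort("`censoring` must lie in [0, 1).")

  with_seed_(seed, {
    genes <- sprintf("gene_%03d", seq_len(n_genes))
    samples <- sprintf("s%04d", seq_len(n_samples))
    ml <- rep_len(meanlog, n_genes)
    sl <- rep_len(sdlog, n_genes)
    m <- matrix(rlnorm(n_genes * n_samples, meanlog = ml, sdlog = sl),
                nrow = n_genes, dimnames = list(genes, samples))

    truth_planted <- tibble(gene = character(), cutpoint = double(),
                            beta = double())
    loghaz <- rep(log(baseline_hazard), n_samples)
    true_score <- rep(0, n_samples)
    if (!is.null(planted) && nrow(planted) > 0) {
      pg <- planted$gene
      if (is.numeric(pg)) pg <- genes[pg]
      if (!all(pg %in% genes)) abort("planted genes must lie within the simulated genes.")
      qs <- if ("cutpoint_quantile" %in% names(planted)) {
        planted$cutpoint_quantile
      } else {
        rep(0.5, nrow(planted))
      }
      cuts <- vapply(seq_along(pg),
                     function(i) unname(quantile(m[pg[i], ], qs[i])), 0)
      for (i in seq_along(pg)) {
        above <- m[pg[i], ] > cuts[i]
        loghaz <- loghaz + planted$beta[i] * above
        true_score <- true_score + planted$beta[i] * ifelse(above, 1, -1)
      }
      truth_planted <- tibble(gene = pg, cutpoint = cuts, beta = planted$beta)
    }

    tt <- rexp(n_samples, rate = exp(loghaz))
    if (censoring > 0) {
      # C ~ Unif(0, tau); expected censored fraction is mean(min(T/tau, 1)),
      # decreasing in tau, so the target is bracketed and solvable
      f <- function(tau) mean(pmin(tt / tau, 1)) - censoring
      upper <- max(tt) * 2
      while (f(upper) > 0) upper <- upper * 2
      tau <- uniroot(f, lower = min(tt) * 1e-6, upper = upper, tol = 1e-8)$root
      cc <- runif(n_samples, 0, tau)
      time <- pmin(tt, cc)
      event <- as.integer(tt <= cc)
    } else {
      time <- tt
      event <- rep(1L, n_samples)
    }
    if (sum(event) == 0) abort("censoring target left no observed events.")

    expr <- as_tibble(cbind(tibble(probeset_id = genes), as.data.frame(m)))
    out <- list(
      expr = expr,
      surv = tibble(sample_id = samples, time = time, event = event),
      truth = list(planted = truth_planted, baseline_hazard = baseline_hazard,
                   censoring_target = censoring,
                   true_score = setNames(true_score, samples), seed = seed)
    )
    class(out) <- "ez_cohort"
    out
  })
}

#' Generate drug-sensitivity records coupled to a score
#'
#' Viability = intercept + slope * score + Gaussian noise. With a negative
#' slope, higher-score samples lose more viability under treatment, giving a
#' negative score-viability correlation by construction.
#'
#' @param scores Tibble with `sample_id` and `score`, or a numeric vector of
#'   true scores.
#' @param slope,intercept Linear coupling (defaults -20, 100: percent viable
#'   relative to control).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return Tibble: `sample_id`, `viability`.
#' @export
generate_sensitivity <- function(scores, slope = -20, intercept = 100,
                                 noise_sd = 10, seed = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative.")
  if (is.numeric(scores)) {
    scores <- tibble(sample_id = names(scores) %||%
                       sprintf("s%04d", seq_along(scores)),
                     score = as.numeric(scores))
  }
  with_seed_(seed, {
    tibble(sample_id = scores$sample_id,
           viability = intercept + slope * scores$score +
             rnorm(nrow(scores), sd = noise_sd))
  })
}

#' Noise level attaining a target score-viability correlation
#'
#' For viability = intercept + slope * score + N(0, sd^2), the population
#' correlation is `sign(slope) / sqrt(1 + sd^2 / (slope^2 var(score)))`;
#' inverting gives the noise standard deviation that attains `target_r`.
#'
#' @param scores Numeric scores (or tibble with a `score` column).
#' @param slope Linear coupling slope (its sign must match `target_r`).
#' @param target_r Target correlation in (-1, 0) or (0, 1).
#' @return Noise standard deviation.
#' @export
calibrate_sensitivity_noise <- function(scores, slope, target_r) {
  s <- if (is.data.frame(scores)) scores$score else scores
  if (abs(target_r) >= 1 || target_r == 0) abort("`target_r` must be in (-1,1), nonzero.")
  if (sign(slope) != sign(target_r)) abort("`slope` and `target_r` must share a sign.")
  abs(slope) * sd(s) * sqrt(1 / target_r^2 - 1)
}

#' Generate bimodal promoter-methylation profiles
#'
#' CpG betas are drawn from a two-component Beta mixture (low around 0.1,
#' high around 0.9). Resistant lines receive an elevated high-component
#' probability on target-gene promoter CpGs, mimicking silencing of the
#' drug's target genes in resistant cells.
#'
#' @param n_sensitive,n_resistant Cell lines per group.
#' @param n_target_genes,n_background_genes Gene counts; targets get the
#'   resistant shift, background genes do not.
#' @param resistant_shift Added high-component probability on target
#'   promoters in resistant lines (0 makes groups exchangeable).
#' @param base_high_prob High-component probability everywhere else.
#' @param cpgs_per_gene CpGs simulated inside each promoter.
#' @param seed RNG seed.
#' @return List of class `ez_meth_sim`: `meth` (wide beta table), `cpg_coords`,
#'   `promoters` (0-based half-open), `groups` (sample_id, group),
#'   `target_genes`, `truth`.
#' @export
generate_methylation <- function(n_sensitive = 3, n_resistant = 3,
                                 n_target_genes = 150, n_background_genes = 50,
                                 resistant_shift = 0.3, base_high_prob = 0.15,
                                 cpgs_per_gene = 3, seed = NULL) {
  if (resistant_shift < 0 || base_high_prob + resistant_shift > 1) {
    abort("high-component probabilities must stay within [0, 1].")
  }
  with_seed_(seed, {
    n_genes <- n_target_genes + n_background_genes
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    target <- genes[seq_len(n_target_genes)]
    samples <- c(sprintf("sens_%02d", seq_len(n_sensitive)),
                 sprintf("res_%02d", seq_len(n_resistant)))
    group <- rep(c("sensitive", "resistant"), c(n_sensitive, n_resistant))

    promoters <- tibble(gene_symbol = genes, chrom = "chr1",
                        start = (seq_len(n_genes) - 1L) * 2000L,
                        end = (seq_len(n_genes) - 1L) * 2000L + 1000L)
    cpg <- tibble(
      cpg_id = sprintf("cg%05d", seq_len(n_genes * cpgs_per_gene)),
      gene_symbol = rep(genes, each = cpgs_per_gene),
      chrom = "chr1",
      pos = rep(promoters$start, each = cpgs_per_gene) +
        as.integer(runif(n_genes * cpgs_per_gene, 0, 1000))
    )

    n_cpg <- nrow(cpg)
    is_target <- cpg$gene_symbol %in% target
    b <- matrix(0, nrow = n_cpg, ncol = length(samples),
                dimnames = list(cpg$cpg_id, samples))
    for (j in seq_along(samples)) {
      p_high <- rep(base_high_prob, n_cpg)
      if (group[j] == "resistant") {
        p_high[is_target] <- base_high_prob + resistant_shift
      }
      high <- rbinom(n_cpg, 1, p_high) == 1
      b[, j] <- ifelse(high, rbeta(n_cpg, 45, 5), rbeta(n_cpg, 5, 45))
    }

    out <- list(
      meth = as_tibble(cbind(tibble(cpg_id = cpg$cpg_id), as.data.frame(b))),
      cpg_coords = cpg[c("cpg_id", "chrom", "pos")],
      promoters = promoters,
      groups = tibble(sample_id = samples, group = group),
      target_genes = target,
      truth = list(resistant_shift = resistant_shift,
                   base_high_prob = base_high_prob, seed = seed)
    )
    class(out) <- "ez_meth_sim"
    out
  })
}
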
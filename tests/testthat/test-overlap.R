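test_that("mark overlap counts agree with set algebra", {
  out <- mark_overlap_counts(c("a", "b", "c", "d"), c("b", "c", "d"),
                             c("c", "d", "e"))
  expect_equal(out$de_k27, 3)
  expect_equal(out$de_bivalent, 2)
  expect_equal(out$union_size, 5)

  disjoint <- mark_overlap_counts(c("a", "b"), c("c"), c("d"))
  expect_equal(disjoint$de_k27, 0)
  expect_equal(disjoint$de_k4, 0)
  expect_equal(disjoint$de_k27_k4, 0)
})

test_that("every Venn region equals brute-force enumeration and sums to the union", {
  set.seed(52)
  universe <- sprintf("g%04d", 1:1500)
  de <- sample(universe, 300)
  k27 <- sample(universe, 500)
  k4 <- sample(universe, 400)
  out <- mark_overlap_counts(de, k27, k4)

  regions <- c(0, 0, 0, 0, 0, 0, 0)
  for (g in unique(c(de, k27, k4))) {
    key <- paste0(as.integer(g %in% de), as.integer(g %in% k27),
                  as.integer(g %in% k4))
    i <- match(key, c("100", "010", "001", "110", "101", "011", "111"))
    regions[i] <- regions[i] + 1
  }
  expect_equal(unlist(out[c("de_only", "k27_only", "k4_only", "de_k27_only",
                            "de_k4_only", "k27_k4_only", "de_k27_k4")],
                      use.names = FALSE), regions)
  expect_equal(sum(regions), out$union_size)
  # intersections commute
  expect_equal(mark_overlap_counts(k27, de, k4)$de_k27, out$de_k27)
})

test_that("promoter methylation calls use strict > threshold and half-open intervals", {
  prom <- tibble::tibble(gene_symbol = "G1", chrom = "chr1",
                         start = 100L, end = 200L)
  co <- tibble::tibble(cpg_id = c("c1", "c2", "c3", "c4"),
                       chrom = "chr1", pos = c(150L, 99L, 100L, 200L))
  meth <- tibble::tibble(cpg_id = c("c1", "c2", "c3", "c4"),
                         s1 = c(0.85, 0.9, 0.1, 0.9))
  st <- classify_promoter_methylation(meth, co, prom, 0.8)
  expect_equal(as.character(st$status), "methylated")  # c1 at 0.85 > 0.8

  # beta exactly at the threshold does not call methylation
  meth2 <- meth; meth2$s1 <- c(0.8, 0, 0, 0)
  st2 <- classify_promoter_methylation(meth2, co, prom, 0.8)
  expect_equal(as.character(st2$status), "unmethylated")

  # boundary arithmetic: pos 99 outside, pos 100 inside, pos 200 outside
  meth3 <- meth; meth3$s1 <- c(0, 0.99, 0, 0)   # only the CpG at 99 is high
  expect_equal(as.character(classify_promoter_methylation(meth3, co, prom)$status),
               "unmethylated")
  meth4 <- meth; meth4$s1 <- c(0, 0, 0.99, 0)   # CpG at 100 (= start) is high
  expect_equal(as.character(classify_promoter_methylation(meth4, co, prom)$status),
               "methylated")
  meth5 <- meth; meth5$s1 <- c(0, 0, 0, 0.99)   # CpG at 200 (= end) excluded
  expect_equal(as.character(classify_promoter_methylation(meth5, co, prom)$status),
               "unmethylated")

  # a promoter with no CpG is reported as no-data
  prom2 <- dplyr::bind_rows(prom,
    tibble::tibble(gene_symbol = "G2", chrom = "chr2", start = 0L, end = 50L))
  st6 <- classify_promoter_methylation(meth, co, prom2)
  expect_equal(as.character(st6$status[st6$gene_symbol == "G2"]), "no-data")

  expect_error(classify_promoter_methylation(meth, co, prom, 1.2), "in \\(0, 1\\)")
})

test_that("random CpG-promoter assignment equals the all-pairs interval check", {
  set.seed(61)
  n_cpg <- 1000
  promoters <- tibble::tibble(gene_symbol = sprintf("G%02d", 1:50),
                              chrom = sample(c("chr1", "chr2"), 50, TRUE),
                              start = as.integer(sample(0:9000, 50)))
  promoters$end <- promoters$start + 150L
  co <- tibble::tibble(cpg_id = sprintf("c%04d", 1:n_cpg),
                       chrom = sample(c("chr1", "chr2"), n_cpg, TRUE),
                       pos = as.integer(sample(0:9500, n_cpg, TRUE)))
  meth <- tibble::tibble(cpg_id = co$cpg_id, s1 = runif(n_cpg))
  st <- classify_promoter_methylation(meth, co, promoters, 0.8)

  for (i in sample(50, 12)) {
    inside <- co$chrom == promoters$chrom[i] &
      co$pos >= promoters$start[i] & co$pos < promoters$end[i]
    expect_equal(st$n_cpg[st$gene_symbol == promoters$gene_symbol[i]][1],
                 sum(inside))
    expected <- if (sum(inside) == 0) "no-data" else {
      if (any(meth$s1[inside] > 0.8)) "methylated" else "unmethylated"
    }
    expect_equal(as.character(
      st$status[st$gene_symbol == promoters$gene_symbol[i]][1]), expected)
  }

  # raising the threshold never adds methylated calls
  st_hi <- classify_promoter_methylation(meth, co, promoters, 0.9)
  expect_true(all(!(st_hi$status == "methylated" & st$status != "methylated")))
})

test_that("sensitive-vs-resistant comparison handles identity and recovers planted shifts", {
  sim0 <- generate_methylation(resistant_shift = 0, seed = 5)
  st0 <- classify_promoter_methylation(sim0$meth, sim0$cpg_coords,
                                       sim0$promoters)
  # force literally identical per-sample profiles across groups
  b <- sim0$meth
  for (s in sim0$groups$sample_id) b[[s]] <- b[[1 + 1]]  # copy first sample
  st_same <- classify_promoter_methylation(b, sim0$cpg_coords, sim0$promoters)
  res_same <- compare_methylation_by_sensitivity(st_same, sim0$groups,
                                                 sim0$target_genes)
  expect_equal(res_same$p_value, 1)

  # planted +0.3 high-component shift: direction recovered in most replicates
  hits <- sapply(1:60, function(s) {
    sim <- generate_methylation(resistant_shift = 0.3, seed = 100 + s)
    st <- classify_promoter_methylation(sim$meth, sim$cpg_coords, sim$promoters)
    res <- compare_methylation_by_sensitivity(st, sim$groups, sim$target_genes)
    fr <- tapply(res$per_sample$fraction_methylated, res$per_sample$group, mean)
    fr["resistant"] > fr["sensitive"]
  })
  expect_gte(mean(hits), 0.95)

  expect_error(compare_methylation_by_sensitivity(
    st0, dplyr::mutate(sim0$groups, group = "one"), NULL), "two non-empty")
})

test_that("rank-sum statistic matches exhaustive enumeration on a 6-sample toy", {
  x <- c(0.10, 0.40, 0.55)  # group A fractions
  y <- c(0.20, 0.70, 0.90)  # group B fractions
  st <- tibble::tibble(
    gene_symbol = rep(sprintf("g%02d", 1:20), times = 6),
    sample_id = rep(sprintf("s%d", 1:6), each = 20),
    n_cpg = 1L,
    status = factor(unlist(lapply(c(x, y), function(f)
      rep(c("methylated", "unmethylated"), round(c(f, 1 - f) * 20)))),
      levels = c("methylated", "unmethylated", "no-data")))
  groups <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                           group = rep(c("A", "B"), each = 3))
  res <- compare_methylation_by_sensitivity(st, groups)

  # exact two-sided p by enumerating all 20 assignments of 3-of-6 ranks
  fr <- c(x, y)
  combos <- combn(6, 3)
  u_obs <- sum(rank(fr)[1:3]) - 6
  u_null <- apply(combos, 2, function(idx) sum(rank(fr)[idx]) - 6)
  mu <- mean(u_null)
  p_exact <- min(1, 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs)))
  expect_equal(res$p_value, p_exact, tolerance = 1e-10)
})

test_that("methylation-DE overlap counts nested intersections", {
  out <- methylation_de_overlap(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(out$n_meth_de, 2)
  expect_true(is.na(out$n_meth_de_reactivated))

  deci <- tibble::tibble(gene = c("b", "c", "d"),
                         fold_change = c(1.6, 1.2, 3.0),
                         padj = c(0.5, 0.5, 0.5))
  out2 <- methylation_de_overlap(c("a", "b", "c"), c("b", "c", "d"), deci)
  expect_equal(out2$n_meth_de_reactivated, 1)  # only b passes ratio > 1.5

  expect_equal(methylation_de_overlap(character(), c("x"))$n_meth_de, 0)

  # brute-force check on random sets
  set.seed(71)
  mg <- sample(sprintf("g%03d", 1:400), 150)
  de <- sample(sprintf("g%03d", 1:400), 263)
  bf <- sum(vapply(mg, function(g) g %in% de, logical(1)))
  expect_equal(methylation_de_overlap(mg, de)$n_meth_de, bf)
})

test_that("promoter windows derive from TSS with strand orientation", {
  ann <- tibble::tibble(gene_symbol = c("F", "R"), chrom = "chr1",
                        tss = c(10000L, 20000L), strand = c("+", "-"))
  pm <- promoters_from_tss(ann)
  # forward strand: [tss - 1500, tss + 500)
  expect_equal(pm$start[1], 8500L)
  expect_equal(pm$end[1], 10500L)
  # reverse strand: upstream lies to the right of the TSS
  expect_equal(pm$start[2], 19501L)
  expect_equal(pm$end[2], 21501L)
  # windows feed straight into the methylation classifier
  co <- tibble::tibble(cpg_id = "c1", chrom = "chr1", pos = 8500L)
  meth <- tibble::tibble(cpg_id = "c1", s1 = 0.95)
  st <- classify_promoter_methylation(meth, co, pm)
  expect_equal(as.character(st$status[st$gene_symbol == "F"]), "methylated")
})
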
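# FST outlier flagging, interval overlap, hypergeometric tails, Venn
# partitions, direction summaries and GO keyword selection

mk_windows <- function(fst, chrom = "2L", size = 1000) {
  n <- length(fst)
  data.frame(chrom = chrom, start = (seq_len(n) - 1) * size + 1,
             end = seq_len(n) * size, mean_fst = fst)
}

test_that("outlier flagging takes the top fraction with positional tie-break", {
  set.seed(2)
  w <- mk_windows(runif(1000))
  fl <- flag_outlier_windows(w, 0.05)
  expect_identical(sum(fl$outlier), 50L)
  # sort-and-slice oracle
  expect_setequal(which(fl$outlier), order(-w$mean_fst)[1:50])

  tied <- flag_outlier_windows(mk_windows(rep(0.3, 1000)), 0.05)
  expect_identical(sum(tied$outlier), 50L)
  expect_identical(which(tied$outlier), 1:50)  # earliest positions win

  expect_error(flag_outlier_windows(w, 0), "fraction")
  expect_error(flag_outlier_windows(w, 1.2), "fraction")
})

test_that("gene-window overlap uses closed intervals sharing >= 1 bp", {
  w <- data.frame(chrom = "2L", start = c(150, 200), end = c(1149, 1199),
                  mean_fst = c(0.5, 0.5))
  g1 <- data.frame(gene_id = "g1", chrom = "2L", start = 100, end = 199)
  expect_identical(overlap_genes_windows(g1, w[1, ]), "g1")
  expect_identical(overlap_genes_windows(g1, w[2, ]), character(0))  # 199 < 200
  # gene counted once despite hitting both windows
  g2 <- data.frame(gene_id = "g2", chrom = "2L", start = 100, end = 300)
  expect_identical(overlap_genes_windows(g2, w), "g2")
})

test_that("genes on unknown chromosomes are skipped with a warning", {
  w <- mk_windows(c(0.2, 0.9))
  g <- data.frame(gene_id = c("a", "b"), chrom = c("2L", "4"),
                  start = c(10, 10), end = c(2000, 2000))
  expect_warning(ids <- overlap_genes_windows(g, w), "absent")
  expect_identical(ids, "a")
})

test_that("overlap matches the quadratic all-pairs oracle on random fixtures", {
  set.seed(4)
  for (i in 1:50) {
    ng <- sample(5:25, 1); nw <- sample(3:15, 1)
    gs <- sample(1:500, ng, replace = TRUE)
    ws <- sample(1:500, nw, replace = TRUE)
    genes <- data.frame(gene_id = paste0("g", seq_len(ng)),
                        chrom = sample(c("2L", "3R"), ng, replace = TRUE),
                        start = gs, end = gs + sample(0:80, ng, replace = TRUE))
    windows <- data.frame(chrom = sample(c("2L", "3R"), nw, replace = TRUE),
                          start = ws, end = ws + sample(0:60, nw, replace = TRUE),
                          mean_fst = runif(nw))
    expect_setequal(overlap_genes_windows(genes, windows),
                    brute_overlap(genes, windows))
  }
})

test_that("hypergeometric tails match exhaustive enumeration of all draws", {
  # N=10, K=4, n=5: enumerate all C(10,5) samples
  pop <- c(rep(TRUE, 4), rep(FALSE, 6))
  draws <- combn(10, 5)
  k_obs <- colSums(matrix(pop[draws], nrow = 5))
  res <- hypergeom_test(10, 4, 5, 3)
  expect_equal(res$p_upper, mean(k_obs >= 3))  # 66/252
  expect_equal(res$p_upper, 66 / 252)
  expect_equal(res$p_lower, mean(k_obs <= 3))
  # inclusive tails overlap at the observed count
  expect_equal(res$p_upper + res$p_lower, 1 + mean(k_obs == 3))
})

test_that("hypergeometric contracts: support, degenerate sample, monotone tail", {
  expect_error(hypergeom_test(10, 4, 5, 5), "outside support")
  expect_error(hypergeom_test(10, 4, 5, -1), "non-negative")
  full <- hypergeom_test(10, 4, 10, 4)  # n = N forces k = K
  expect_equal(full$p_upper, 1)
  p <- sapply(0:20, function(k) hypergeom_test(100, 30, 20, k)$p_upper)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("the genome-scale enrichment reproduces the published magnitudes", {
  # expressed universe 13072, 2119 DE; 1854 in outlier windows, 391 DE there
  res <- hypergeom_test(13072, 2119, 1854, 391)
  expect_lt(res$p_upper, 1.4e-9)
  expect_equal(res$percent_excess, 30.1, tolerance = 0.01)
  # circadian/sleep GO candidates: 237 expressed, 76 DE -> ~2-fold
  cand <- hypergeom_test(13072, 2119, 237, 76)
  expect_equal(cand$fold_enrichment, 2, tolerance = 0.02)
  expect_lt(cand$p_upper, 1e-8)
})

test_that("enrichment_report assembles (N, K, n, k) from gene flags", {
  g <- data.frame(gene_id = paste0("g", 1:8), chrom = "2L",
                  start = 1:8 * 10, end = 1:8 * 10 + 4,
                  expressed = c(rep(TRUE, 7), FALSE),
                  de_ZT01 = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
                  de_ZT13 = FALSE, de_ZT18 = FALSE, de_ZT22 = FALSE)
  res <- enrichment_report(g, sample_ids = c("g1", "g2", "g3", "g8"))
  expect_identical(res$N, 7L)      # expressed only
  expect_identical(res$K, 3L)      # g1 g2 g5 (g8 not expressed)
  expect_identical(res$n, 3L)      # g1 g2 g3 (g8 dropped)
  expect_identical(res$k, 2L)
  # equal proportions give fold 1 / excess 0
  flat <- enrichment_report(g[1:7, ], sample_ids = paste0("g", 1:7))
  expect_equal(flat$fold_enrichment, 1)
  expect_equal(flat$percent_excess, 0)
})

test_that("timepoint Venn partition is disjoint and exhaustive", {
  g <- data.frame(gene_id = c("a", "b", "c", "d"),
                  de_ZT01 = c(TRUE, TRUE, FALSE, FALSE),
                  de_ZT13 = c(TRUE, FALSE, TRUE, FALSE),
                  de_ZT18 = c(TRUE, FALSE, FALSE, FALSE),
                  de_ZT22 = c(TRUE, FALSE, TRUE, FALSE))
  venn <- timepoint_overlap_summary(g)
  expect_identical(venn$count[venn$subset == "ZT01+ZT13+ZT18+ZT22"], 1L)
  expect_identical(venn$count[venn$subset == "ZT01"], 1L)
  expect_identical(venn$count[venn$subset == "ZT13+ZT22"], 1L)
  expect_identical(sum(venn$count), 3L)  # d is DE nowhere

  # random flags vs brute-force subset classification
  set.seed(9)
  r <- data.frame(gene_id = paste0("g", 1:200),
                  de_ZT01 = runif(200) < 0.4, de_ZT13 = runif(200) < 0.3,
                  de_ZT18 = runif(200) < 0.3, de_ZT22 = runif(200) < 0.3)
  venn2 <- timepoint_overlap_summary(r)
  brute <- table(apply(r[-1], 1, function(x)
    paste(c("ZT01", "ZT13", "ZT18", "ZT22")[as.logical(x)], collapse = "+")))
  brute <- brute[names(brute) != ""]
  expect_identical(sum(venn2$count), sum(r$de_ZT01 | r$de_ZT13 | r$de_ZT18 | r$de_ZT22))
  for (s in venn2$subset)
    expect_identical(venn2$count[venn2$subset == s], as.integer(brute[[s]]))
})

test_that("direction summary reports per-side counts, means and rank-sum p", {
  g <- data.frame(gene_id = c("a", "b", "c", "d"),
                  dir_ZT01 = c("higher_in_A", "higher_in_A", "higher_in_B", "none"),
                  fc_ZT01 = c(2, 4, 1.5, NA))
  ds <- direction_summary(g, "ZT01")
  expect_identical(ds$n_higher_A, 2L)
  expect_identical(ds$n_higher_B, 1L)
  expect_equal(ds$mean_fc_A, 3)
  expect_equal(ds$mean_fc_B, 1.5)
  expect_equal(ds$p_value, 2 / 3)  # exact rank-sum, complete separation 2 vs 1

  onesided <- direction_summary(
    data.frame(gene_id = "a", dir_ZT01 = "higher_in_A", fc_ZT01 = 2), "ZT01")
  expect_identical(onesided$n_higher_B, 0L)
  expect_identical(onesided$p_value, NA_real_)
})

test_that("symmetric fold changes give uniform direction p-values", {
  set.seed(14)
  p <- replicate(300, {
    n <- 40
    g <- data.frame(gene_id = seq_len(n),
                    dir_ZT01 = sample(c("higher_in_A", "higher_in_B"), n, TRUE),
                    fc_ZT01 = exp(abs(rnorm(n, 0, 0.7))))
    direction_summary(g, "ZT01")$p_value
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.001)
})

test_that("GO keyword selection is case-insensitive substring matching", {
  go <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                   term_name = c("Circadian Rhythms regulation", "sleep onset",
                                 "dopamine biosynthesis", "wing development",
                                 "regulation of catecholamine secretion"))
  got <- select_candidate_genes(go, c("sleep", "circadian rhythms",
                                      "dopamine", "catecholamine"))
  expect_setequal(got, c("g1", "g2", "g3", "g5"))
  expect_identical(select_candidate_genes(go, character(0)), character(0))
  # annotated to two matching terms -> returned once
  go2 <- rbind(go, data.frame(gene_id = "g2", term_name = "circadian rhythms"))
  expect_identical(sum(select_candidate_genes(go2, c("sleep", "circadian")) == "g2"), 1L)
})
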
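test_that("PRR is a plain width-normalised density ratio", {
  expect_equal(compute_prr(1, 1), 1)
  d <- c(0.1, 1, 17)
  expect_equal(compute_prr(3.34 * d, d), rep(3.34, 3))
  # equal per-bp coverage in both windows gives PRR 1 whatever the widths
  L <- 2e6
  expect_equal(window_density(601, 601, L) / window_density(1001, 1001, L), 1)
  expect_warning(out <- compute_prr(1, 0), "non-positive")
  expect_true(is.na(out))
})

test_that("zero-body genes are excluded by default, kept with a pseudocount", {
  counts <- data.frame(
    gene_id = rep(c("g1", "g2"), each = 2),
    condition = "control", replicate = rep(1:2, 2),
    tss_count = c(5L, 6L, 7L, 8L), body_count = c(3L, 4L, 0L, 5L),
    library_size = 1000L)
  counts$tss_density <- window_density(counts$tss_count, 601, counts$library_size)
  counts$body_density <- window_density(counts$body_count, 1001, counts$library_size)
  prr <- suppressMessages(build_prr_table(counts))
  expect_setequal(unique(prr$gene_id), "g1")
  expect_identical(attr(prr, "excluded"), "g2")
  prr2 <- build_prr_table(counts, pseudocount = TRUE)
  expect_setequal(unique(prr2$gene_id), c("g1", "g2"))
  expect_true(all(is.finite(prr2$prr)))
})

make_prr <- function(ctrl, other, gene = "g1",
                     labels = c("control", "morphant")) {
  data.frame(gene_id = gene,
             condition = rep(labels, times = c(length(ctrl), length(other))),
             replicate = c(seq_along(ctrl), seq_along(other)),
             prr = c(ctrl, other), stringsAsFactors = FALSE)
}

test_that("degenerate replicate sets follow the documented rules", {
  # identical groups with zero variance: unchanged, p = 1
  prr <- make_prr(c(1, 1, 1), c(1, 1, 1))
  rec <- test_prr_per_gene(prr, "control", "morphant")
  expect_equal(rec$p_value, 1)
  expect_identical(rec$direction, "unchanged")
  # exact separation: permutation floor 2/choose(6,3) = 0.1, flagged
  prr2 <- make_prr(c(1, 1, 1), c(2, 2, 2))
  rec2 <- test_prr_per_gene(prr2, "control", "morphant")
  expect_true(rec2$exact_separation)
  expect_equal(rec2$p_value, 0.1)
})

test_that("the per-gene statistic matches the closed-form pooled t-test", {
  # hand-computed: log10 PRRs (0,0,0) vs (1,2,3)/log-scale equivalents
  prr <- make_prr(10^c(0.1, 0.2, 0.3), 10^c(0.5, 0.7, 0.9))
  rec <- test_prr_per_gene(prr, "control", "morphant")
  m1 <- mean(c(0.1, 0.2, 0.3)); m2 <- mean(c(0.5, 0.7, 0.9))
  sp2 <- (2 * var(c(0.1, 0.2, 0.3)) + 2 * var(c(0.5, 0.7, 0.9))) / 4
  t_ref <- (m2 - m1) / sqrt(sp2 * 2 / 3)
  expect_equal(rec$t_statistic, t_ref)
  expect_equal(rec$df, 4)
  expect_equal(rec$p_value, 2 * pt(-abs(t_ref), 4))
})

test_that("the paired global test reproduces the one-sample t worked example", {
  # per-gene differences 1, 2, 3: t = mean/(sd/sqrt(3)) = 3.464, p ~ 0.0742
  res <- paired_log10_t(c(0, 0, 0), c(1, 2, 3))
  expect_equal(res$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(res$statistic, 3.4641016, tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 0.0742, tolerance = 1e-3)
  # zero-variance differences are unchanged
  expect_equal(paired_log10_t(c(1, 2), c(1, 2))$p_value, 1)
})

test_that("adjusted p-values dominate raw p-values and respect BH step-up", {
  fx <- sim_counts_fixture(n_genes = 600, seed = 41)
  prr <- suppressMessages(build_prr_table(fx$counts))
  rec <- test_prr_per_gene(prr, "control", "morphant")
  expect_true(all(rec$padj >= rec$p_value))
  expect_equal(rec$padj, p.adjust(rec$p_value, method = "BH"))
  # direction consistency for every significant gene
  sig <- rec$direction != "unchanged"
  expect_true(all(sign(rec$mean_diff_log10[sig]) ==
                    ifelse(rec$direction[sig] == "increased", 1, -1)))
})

test_that("PRR records and summaries are invariant to density rescaling", {
  fx <- sim_counts_fixture(n_genes = 400, seed = 43)
  counts <- fx$counts
  scaled <- counts
  pick <- scaled$condition == "morphant" & scaled$replicate == 2
  scaled$tss_density[pick] <- scaled$tss_density[pick] * 7
  scaled$body_density[pick] <- scaled$body_density[pick] * 7
  r1 <- test_prr_per_gene(suppressMessages(build_prr_table(counts)),
                          "control", "morphant")
  r2 <- test_prr_per_gene(suppressMessages(build_prr_table(scaled)),
                          "control", "morphant")
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("a self-contrast calls nothing significant", {
  fx <- sim_counts_fixture(n_genes = 500, seed = 44)
  counts <- fx$counts[fx$counts$condition == "control", ]
  twin <- counts
  twin$condition <- "control_copy"
  prr <- suppressMessages(build_prr_table(rbind(counts, twin)))
  rec <- test_prr_per_gene(prr, "control", "control_copy")
  expect_identical(sum(rec$direction != "unchanged"), 0L)
  s <- summarize_contrast(rec)
  expect_equal(s$paired_test_p, 1)
  expect_lt(abs(s$fraction_below_control_median - 0.5),
            1 / s$n_genes_analyzed + 1e-9)
  expect_identical(s$n_significant_decreased + s$n_significant_increased, 0L)
})

test_that("contrast summaries report medians, counts and the paired test", {
  fx <- sim_counts_fixture(n_genes = 1200, seed = 45)
  sel <- select_occupied_genes(fx$counts, "control")
  prr <- suppressMessages(build_prr_table(fx$counts, genes = sel$genes))
  rec <- test_prr_per_gene(prr, "control", "morphant")
  s <- summarize_contrast(rec)
  expect_lte(s$n_significant_decreased + s$n_significant_increased,
             s$n_genes_analyzed)
  expect_gte(s$fraction_below_control_median, 0)
  expect_lte(s$fraction_below_control_median, 1)
  expect_equal(s$median_prr_control, median(rec$mean_prr_control))
  expect_lt(s$median_prr_other, s$median_prr_control)  # attenuated pausing
  expect_lt(s$paired_test_p, 0.001)
  expect_lt(s$paired_test_statistic, 0)
})

test_that("ECDF tables are correct on degenerate and simulated input", {
  # single gene with PRR 2: steps from 0 to 1 at 2
  e <- export_ecdf(list(control = 2), grid = c(1, 2, 3))
  expect_equal(e$cum_frac, c(0, 1, 1))
  # evaluated at a condition's own median, the ECDF is 0.5 (+- 1/n)
  set.seed(46)
  v <- rlnorm(501, 1, 0.6)
  e2 <- export_ecdf(list(a = v), grid = median(v))
  expect_lt(abs(e2$cum_frac - 0.5), 1 / length(v) + 1e-9)
  # monotone nondecreasing from 0 to 1 on random draws
  e3 <- export_ecdf(list(a = v, b = rlnorm(300, 0, 1)))
  for (cond in c("a", "b")) {
    cf <- e3$cum_frac[e3$condition == cond]
    expect_true(all(diff(cf) >= 0))
    expect_equal(cf[length(cf)], 1)
  }
})
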
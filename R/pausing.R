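#' Pause release ratio
#'
#' PRR = TSS-window density / downstream-window density. A high PRR indicates
#' RNA Pol II accumulating near the TSS relative to the downstream region
#' (more pausing); the ratio is invariant to library size and to any common
#' rescaling of a sample's densities. Non-positive downstream densities yield
#' NA (an exclusion signal for upstream filtering, not an error).
#'
#' @param tss_density,body_density densities in matching units.
#' @return numeric vector of PRRs.
#' @export
compute_prr <- function(tss_density, body_density) {
  bad <- !(body_density > 0)
  if (any(bad, na.rm = TRUE))
    warning(sum(bad, na.rm = TRUE),
            " value(s) with non-positive downstream density set to NA")
  ifelse(bad, NA_real_, tss_density / body_density)
}

#' Build the per-replicate PRR table
#'
#' Computes one PRR per gene x condition x replicate. By default genes with a
#' non-positive downstream density in any retained replicate are excluded
#' (their ids are recorded in the `excluded` attribute); with
#' `pseudocount = TRUE`, 0.5 fragments are added to both window counts before
#' densities are recomputed, so no gene is excluded for zero counts.
#'
#' @param counts long count table with columns gene_id, condition, replicate,
#'   tss_density, body_density (and tss_count, body_count, library_size when
#'   `pseudocount = TRUE`).
#' @param genes optional gene ids to restrict to (e.g. the retained set from
#'   [select_occupied_genes()]).
#' @param conditions optional condition labels to restrict to.
#' @param pseudocount add 0.5 fragments to both windows before density
#'   computation instead of excluding zero-body genes.
#' @param spec the [window_spec()] used for widths in pseudocount mode.
#' @return data.frame gene_id, condition, replicate, prr, with attribute
#'   `excluded`.
#' @export
build_prr_table <- function(counts, genes = NULL, conditions = NULL,
                            pseudocount = FALSE, spec = window_spec()) {
  req <- c("gene_id", "condition", "replicate", "tss_density", "body_density")
  if (!all(req %in% names(counts)))
    stop("counts must have columns: ", paste(req, collapse = ", "))
  sub <- counts
  if (!is.null(genes)) sub <- sub[sub$gene_id %in% genes, ]
  if (!is.null(conditions)) sub <- sub[sub$condition %in% conditions, ]
  if (nrow(sub) == 0) stop("no count rows left after filtering")
  if (pseudocount) {
    if (!all(c("tss_count", "body_count", "library_size") %in% names(sub)))
      stop("pseudocount mode needs tss_count, body_count, library_size columns")
    tssd <- window_density(sub$tss_count + 0.5, tss_window_width(spec),
                           sub$library_size)
    bodyd <- window_density(sub$body_count + 0.5, body_window_width(spec),
                            sub$library_size)
  } else {
    tssd <- sub$tss_density
    bodyd <- sub$body_density
  }
  prr <- suppressWarnings(compute_prr(tssd, bodyd))
  out <- data.frame(gene_id = sub$gene_id, condition = sub$condition,
                    replicate = sub$replicate, prr = prr,
                    stringsAsFactors = FALSE)
  bad_genes <- unique(out$gene_id[!is.finite(out$prr) | out$prr <= 0])
  if (length(bad_genes) > 0) {
    message(length(bad_genes),
            " gene(s) excluded from the PRR table (a zero TSS or downstream ",
            "density in at least one replicate)")
    out <- out[!out$gene_id %in% bad_genes, ]
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- bad_genes
  out
}

# Exact two-sided permutation floor for a two-sample test with complete
# separation (zero pooled variance, unequal means): the smallest attainable
# two-sided permutation p-value, 2 / choose(n1 + n2, n1).
.separation_p <- function(n1, n2) 2 / choose(n1 + n2, n1)

#' Per-gene replicate t-tests of PRR change between two conditions
#'
#' For each gene, a two-sample two-tailed t-test compares the replicate PRRs
#' of `other` against `control`, on the log10 scale by default (pooled
#' variance by default; Welch with `var_equal = FALSE`). P-values are
#' Benjamini-Hochberg adjusted across all tested genes; a gene is called
#' `decreased`/`increased` when its adjusted p-value is below `alpha_fdr`,
#' with the direction given by the sign of the replicate-mean log10 PRR
#' difference, and `unchanged` otherwise.
#'
#' Degenerate genes: zero variance in both groups with equal means gives
#' p = 1 (`unchanged`); zero pooled variance with unequal means is an exact
#' separation, flagged and assigned the smallest attainable two-sided
#' permutation p-value (0.1 for 3 vs 3).
#'
#' @param prr PRR table from [build_prr_table()].
#' @param control,other condition labels to compare.
#' @param alpha_fdr BH-adjusted significance threshold (default 0.10).
#' @param log_transform test log10 PRRs (default) or raw PRRs.
#' @param var_equal pooled-variance t-test (default) or Welch.
#' @return data.frame (class `prr_records`) with one row per gene: replicate
#'   PRRs per condition, mean PRRs, log10 mean PRRs, t_statistic, df, p_value,
#'   padj, direction, exact_separation; conditions stored in the `conditions`
#'   attribute.
#' @export
test_prr_per_gene <- function(prr, control, other, alpha_fdr = 0.1,
                              log_transform = TRUE, var_equal = TRUE) {
  if (!(alpha_fdr > 0 && alpha_fdr < 1)) stop("alpha_fdr must lie in (0, 1)")
  sub <- prr[prr$condition %in% c(control, other), ]
  if (nrow(sub) == 0) stop("no PRR rows for the requested conditions")
  gid <- factor(sub$gene_id)
  repf <- factor(sub$replicate)
  condf <- factor(sub$condition, levels = c(control, other))
  arr <- tapply(sub$prr, list(gid, repf, condf), mean)
  complete <- apply(!is.na(arr), 1, all)
  if (!any(complete)) stop("no gene has complete replicates in both conditions")
  if (any(!complete))
    message(sum(!complete), " gene(s) dropped: incomplete replicates")
  arr <- arr[complete, , , drop = FALSE]
  n_rep <- dim(arr)[2]
  if (n_rep < 2) stop("need at least 2 replicates per condition")
  xc <- arr[, , 1, drop = TRUE]
  xo <- arr[, , 2, drop = TRUE]
  if (is.null(dim(xc))) { xc <- matrix(xc, ncol = n_rep); xo <- matrix(xo, ncol = n_rep) }
  yc <- if (log_transform) log10(xc) else xc
  yo <- if (log_transform) log10(xo) else xo
  n1 <- n2 <- n_rep
  m1 <- rowMeans(yc); m2 <- rowMeans(yo)
  v1 <- rowSums((yc - m1)^2) / (n1 - 1)
  v2 <- rowSums((yo - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  zero_se <- se < 1e-12 | !is.finite(se)
  equal <- zero_se & abs(m2 - m1) < 1e-12
  separated <- zero_se & !equal
  tstat[equal] <- 0; p[equal] <- 1; df[equal] <- n1 + n2 - 2
  tstat[separated] <- sign(m2 - m1)[separated] * Inf
  p[separated] <- .separation_p(n1, n2)
  padj <- stats::p.adjust(p, method = "BH")
  mean_diff_log10 <- if (log_transform) m2 - m1 else
    rowMeans(log10(xo)) - rowMeans(log10(xc))
  direction <- ifelse(padj < alpha_fdr,
                      ifelse(mean_diff_log10 < 0, "decreased", "increased"),
                      "unchanged")
  out <- data.frame(gene_id = rownames(arr), stringsAsFactors = FALSE)
  for (r in seq_len(n_rep)) out[[sprintf("prr_control_%d", r)]] <- xc[, r]
  for (r in seq_len(n_rep)) out[[sprintf("prr_other_%d", r)]] <- xo[, r]
  out$mean_prr_control <- rowMeans(xc)
  out$mean_prr_other <- rowMeans(xo)
  out$log10_mean_prr_control <- log10(out$mean_prr_control)
  out$log10_mean_prr_other <- log10(out$mean_prr_other)
  out$mean_diff_log10 <- mean_diff_log10
  out$t_statistic <- tstat
  out$df <- df
  out$p_value <- p
  out$padj <- padj
  out$direction <- direction
  out$exact_separation <- separated
  rownames(out) <- NULL
  attr(out, "conditions") <- c(control = control, other = other)
  attr(out, "alpha_fdr") <- alpha_fdr
  class(out) <- c("prr_records", "data.frame")
  out
}

#' Paired t-test on per-gene log10 mean PRR differences
#'
#' The genome-wide contrast statistic: per-gene differences of log10 mean
#' PRRs (`other - control`) tested against zero with a two-tailed one-sample
#' t-test (pairing is by gene). Zero-variance differences are handled as
#' unchanged (statistic 0, p = 1).
#'
#' @param log10_control,log10_other per-gene log10 mean PRRs.
#' @return list with statistic, df, p_value, mean_diff, n.
#' @export
paired_log10_t <- function(log10_control, log10_other) {
  d <- log10_other - log10_control
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 2) stop("need at least 2 paired genes")
  if (stats::sd(d) < 1e-12)
    return(list(statistic = 0, df = n - 1, p_value = 1,
                mean_diff = mean(d), n = n))
  tt <- stats::t.test(d)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(d), n = n)
}

#' Cumulative-frequency (ECDF) table for PRR distributions
#'
#' Evaluates each condition's empirical CDF on a shared grid, log-spaced over
#' the pooled range of values by default.
#'
#' @param prr_by_condition named list of positive numeric vectors (one per
#'   condition), e.g. mean PRRs per gene.
#' @param n_grid number of grid points.
#' @param grid optional explicit grid (overrides `n_grid`).
#' @return data.frame: grid value `prr`, condition, cumulative fraction
#'   `cum_frac`.
#' @export
export_ecdf <- function(prr_by_condition, n_grid = 200, grid = NULL) {
  if (is.null(names(prr_by_condition)) || length(prr_by_condition) < 1)
    stop("prr_by_condition must be a non-empty named list")
  vals <- unlist(prr_by_condition)
  vals <- vals[is.finite(vals) & vals > 0]
  if (length(vals) == 0) stop("no positive finite PRR values")
  if (is.null(grid)) {
    rng <- range(vals)
    grid <- if (rng[1] == rng[2]) rng[1] else
      10^seq(log10(rng[1]), log10(rng[2]), length.out = n_grid)
  }
  do.call(rbind, lapply(names(prr_by_condition), function(cond) {
    v <- prr_by_condition[[cond]]
    v <- v[is.finite(v)]
    data.frame(prr = grid, condition = cond,
               cum_frac = vapply(grid, function(g) mean(v <= g), numeric(1)),
               stringsAsFactors = FALSE)
  }))
}

#' Genome-wide summary of a pausing contrast
#'
#' Aggregates per-gene records into the headline quantities of a contrast:
#' median PRR per condition, counts of significantly decreased/increased
#' genes, the fraction of genes whose contrast-condition mean PRR falls below
#' the control median, the global paired t-test on log10 mean PRRs
#' ([paired_log10_t()]), and shared-grid ECDFs.
#'
#' @param records a `prr_records` table from [test_prr_per_gene()].
#' @param n_grid ECDF grid size.
#' @return object of class `prr_contrast_summary`.
#' @export
summarize_contrast <- function(records, n_grid = 200) {
  if (!inherits(records, "prr_records") || nrow(records) == 0)
    stop("records must be a non-empty prr_records table")
  conds <- attr(records, "conditions")
  med_c <- stats::median(records$mean_prr_control)
  med_o <- stats::median(records$mean_prr_other)
  paired <- paired_log10_t(records$log10_mean_prr_control,
                           records$log10_mean_prr_other)
  ecdf_tab <- export_ecdf(stats::setNames(
    list(records$mean_prr_control, records$mean_prr_other), conds), n_grid)
  out <- list(
    control = unname(conds["control"]), other = unname(conds["other"]),
    alpha_fdr = attr(records, "alpha_fdr"),
    n_genes_analyzed = nrow(records),
    n_significant_decreased = sum(records$direction == "decreased"),
    n_significant_increased = sum(records$direction == "increased"),
    median_prr_control = med_c,
    median_prr_other = med_o,
    fraction_below_control_median = mean(records$mean_prr_other < med_c),
    paired_test_statistic = paired$statistic,
    paired_test_df = paired$df,
    paired_test_p = paired$p_value,
    ecdf = ecdf_tab)
  class(out) <- "prr_contrast_summary"
  out
}

#' @export
print.prr_contrast_summary <- function(x, ...) {
  cat(sprintf("PRR contrast: %s vs %s (%d genes)\n",
              x$other, x$control, x$n_genes_analyzed))
  cat(sprintf("  significant at FDR %.2f: %d decreased, %d increased\n",
              x$alpha_fdr, x$n_significant_decreased, x$n_significant_increased))
  cat(sprintf("  median PRR: %s %.3f, %s %.3f\n",
              x$control, x$median_prr_control, x$other, x$median_prr_other))
  cat(sprintf("  %.1f%% of genes below the %s median\n",
              100 * x$fraction_below_control_median, x$control))
  cat(sprintf("  paired t on log10 mean PRR: t=%.3f df=%.0f p=%.3g\n",
              x$paired_test_statistic, x$paired_test_df, x$paired_test_p))
  invisible(x)
}
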
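#!/usr/bin/env Rscript

# Step 3: pausing analysis of the simulated study.
#
# Selects Pol II-occupied genes by the two-component mixture cutoff on log10
# control TSS densities (10% type-I error), computes per-gene pause release
# ratios, tests each gene's PRR change with pooled 3v3 t-tests on log10 PRRs
# (BH, significance at adjusted p < 0.1), and summarises both contrasts
# genome-wide.

suppressPackageStartupMessages(library(pausekit))

indir <- "results/sim"
outdir <- "results/pausing"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
counts <- read.delim(file.path(indir, "counts.tsv"))

sel <- select_occupied_genes(counts, "control", type1_error = 0.1)
print(sel)
jsonlite::write_json(unclass(sel$fit), file.path(outdir, "mixture_fit.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

prr <- build_prr_table(counts, genes = sel$genes)
cat(sprintf("PRR table: %d genes x %d condition-replicates\n",
            length(unique(prr$gene_id)), nrow(prr) / length(unique(prr$gene_id))))

summaries <- list()
for (contrast in list(c("control", "morphant"),
                      c("morphant", "morphant_flavopiridol"))) {
  rec <- test_prr_per_gene(prr, contrast[1], contrast[2], alpha_fdr = 0.1)
  s <- summarize_contrast(rec)
  print(s)
  write.table(as.data.frame(rec),
              file.path(outdir, sprintf("prr_%s_vs_%s.tsv",
                                        contrast[2], contrast[1])),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summaries[[paste(contrast[2], "vs", contrast[1])]] <- s
}

ecdf_all <- do.call(rbind, lapply(names(summaries), function(nm) {
  e <- summaries[[nm]]$ecdf; e$contrast <- nm; e
}))
write.table(ecdf_all, file.path(outdir, "ecdf.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(lapply(summaries, function(s) {
  s <- unclass(s); s$ecdf <- NULL; s
}), file.path(outdir, "summary.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)

# how well the analysis recovers the generator's truth
truth <- read.delim(file.path(indir, "ground_truth.tsv"))
s_mo <- summaries[["morphant vs control"]]
cat(sprintf("attenuation recovery: median PRR ratio %.3f vs true median effect %.3f\n",
            s_mo$median_prr_other / s_mo$median_prr_control,
            median(truth$effect_morphant)))
cat("wrote", outdir, "\n")
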
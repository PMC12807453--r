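#!/usr/bin/env Rscript

# Step 5 (optional): presentation figures.
#
# Cumulative-frequency overlay of PRR distributions and per-contrast dot
# plots coloured by significance call. Purely presentational; every number is
# already in the TSV/JSON outputs of steps 3-4.

suppressPackageStartupMessages(library(pausekit))

if (!requireNamespace("ggplot2", quietly = TRUE)) {
  message("ggplot2 not installed; skipping figures")
  quit(status = 0)
}

outdir <- "results/figures"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
counts <- read.delim("results/sim/counts.tsv")

sel <- select_occupied_genes(counts, "control")
prr <- build_prr_table(counts, genes = sel$genes)
records <- list(); summaries <- list()
for (contrast in list(c("control", "morphant"),
                      c("morphant", "morphant_flavopiridol"))) {
  rec <- test_prr_per_gene(prr, contrast[1], contrast[2])
  records[[contrast[2]]] <- rec
  summaries[[contrast[2]]] <- summarize_contrast(rec)
}
paths <- write_figures(summaries, records, outdir)
cat("wrote:", paste(paths, collapse = ", "), "\n")
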
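#!/usr/bin/env Rscript

# Step 1: generate the synthetic pausing study.
#
# Draws a 5000-gene study at the generator's calibrated defaults: bimodal TSS
# occupancy, lognormal pausing factors (control median 3.34), triplicate
# negative-binomial counts for control, knockdown (morphant) and
# inhibitor-treated knockdown conditions, and the three DE tables the rescue
# stage consumes. Everything downstream reads the files written here.

suppressPackageStartupMessages(library(pausekit))

outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_genes = 5000, seed = 1)
gen <- simulate_genes(cfg)
counts <- simulate_counts_table(cfg, gen$truth)
de <- simulate_de_tables(cfg, gen$truth)

write_gene_bed(gen$annotations, file.path(outdir, "annotations.bed"))
write.table(gen$truth, file.path(outdir, "ground_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(counts, file.path(outdir, "counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (nm in names(de))
  write.table(de[[nm]], file.path(outdir, paste0("de_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d genes (%.0f%% occupied in truth) on %d chromosomes\n",
            nrow(gen$annotations), 100 * mean(gen$truth$occupied),
            length(unique(gen$annotations$chrom))))
cat(sprintf("conditions: %s; %d replicates each\n",
            paste(unique(counts$condition), collapse = ", "),
            cfg$n_replicates))
cat(sprintf("median library size: %s fragments\n",
            format(median(tapply(counts$library_size,
                                 paste(counts$condition, counts$replicate),
                                 unique)), big.mark = ",")))
cat("wrote", outdir, "\n")
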
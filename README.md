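# pausekit

Quantification and differential analysis of RNA polymerase II
promoter-proximal pausing from ChIP-seq data.

In many vertebrate genes, RNA Pol II initiates transcription and then stalls
30–60 bp downstream of the transcription start site (TSS) before being
released into productive elongation by the CDK9 kinase of P-TEFb. The
balance between pausing and release is a genuine regulatory layer: losing a
pausing factor, or inhibiting CDK9 with a small molecule such as
flavopiridol, shifts Pol II occupancy genome-wide and re-wires developmental
gene expression. pausekit implements the standard window-based analysis of
this balance for anyone with aligned ChIP-seq fragments and gene
annotations: it measures per-gene pausing, selects the genes with enough
Pol II signal to analyse, tests pausing changes between conditions with
replicate statistics, and evaluates whether an inhibitor treatment
"rescues" the expression changes caused by a knockdown.

## The statistic

For each gene, two strand-aware windows are anchored at the TSS:

* **TSS window**: −300 bp to +300 bp around the TSS (601 bp);
* **downstream window**: +301 bp to +1301 bp in the direction of
  transcription (1001 bp).

With fragment densities `d = count / width / (library_size / 10⁶)` (fragments
per bp per million mapped), the **pause release ratio** of a gene is

```
PRR = d_TSS / d_downstream
```

High PRR means Pol II piles up at the TSS relative to the gene body (more
paused); the ratio is invariant to sequencing depth. The same quantity is
called "pausing index" or "traveling ratio" elsewhere in the literature.

The analysis pipeline is:

1. **Occupancy selection.** Log10 TSS densities across genes are bimodal:
   an upper mode of genes with real Pol II signal over a background mode.
   A two-component Gaussian mixture is fitted by EM and genes above the
   90th percentile of the lower component (type-I error 10%) are retained.
2. **Per-gene tests.** Replicate PRRs (3 vs 3 by default) are compared
   between conditions with two-tailed pooled-variance t-tests on log10 PRRs;
   Benjamini–Hochberg adjusted p-values below 0.1 are significant, with the
   direction taken from the sign of the mean log10 PRR difference.
3. **Genome-wide summary.** Median PRR per condition, counts of
   significantly decreased/increased genes, the fraction of genes below the
   control median, cumulative-frequency (ECDF) curves, and a global paired
   t-test on per-gene log10 mean PRR differences.
4. **Rescue sets.** Given DE tables for a knockdown-vs-control and an
   inhibitor-vs-vehicle contrast, a gene is *rescued* when the inhibitor
   causes a significant change (adjusted p < 0.1) opposite in direction to
   the knockdown's significant change (adjusted p < 0.05), with the full
   4-set Venn partition reported.

A seeded simulator (`sim_config()`, `simulate_genes()`, …) generates
annotations, fragment BEDs or count tables, and DE tables with known ground
truth — calibrated so the control median PRR is ≈ 3.34 and the log TSS
densities are bimodal — making every stage testable without external data.

## Worked example

```r
library(pausekit)

cfg    <- sim_config(n_genes = 2000, seed = 1)
gen    <- simulate_genes(cfg)
counts <- simulate_counts_table(cfg, gen$truth)

sel <- select_occupied_genes(counts, "control")
sel$fit
#> Two-component Gaussian mixture on log10 TSS densities
#>   lower : mu=-2.3067 sd=0.4188 weight=0.305
#>   upper : mu=-0.1900 sd=0.3099 weight=0.695
#>   cutoff: -1.7700 (type-I error 0.10), loglik -1879.46, 11 iter

prr <- build_prr_table(counts, genes = sel$genes)
rec <- test_prr_per_gene(prr, "control", "morphant", alpha_fdr = 0.1)
summarize_contrast(rec)
#> PRR contrast: morphant vs control (1434 genes)
#>   significant at FDR 0.10: 1298 decreased, 1 increased
#>   median PRR: control 3.295, morphant 1.367
#>   93.9% of genes below the control median
#>   paired t on log10 mean PRR: t=-93.226 df=1433 p=0
```

Reading this output: of 2000 simulated genes, 1434 pass the occupancy
cutoff; the knockdown condition attenuates pausing so strongly that 90% of
analysed genes are called significantly decreased and ~94% fall below the
control median PRR of ≈ 3.3 — the asymmetric, genome-wide shift the
statistic is designed to expose — while the background mode (mean log10
density −2.3) sits two decades below the occupied mode, which is what makes
the mixture cutoff well-defined.

The `analysis/` directory holds the same workflow as numbered scripts
(`01_simulate.R` … `05_figures.R`), each writing its tables under
`results/`; `run_pipeline()` runs all stages end-to-end from a single
validated configuration with deterministic outputs.

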
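---
title: "Measuring promoter-proximal pausing: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring promoter-proximal pausing: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the model behind each stage, the tunable parameters and why their defaults
are what they are, what the bundled simulator does and does not emulate,
and the numerical choices that matter at the edges.

## The measurement model

Promoter-proximal pausing is read out from the spatial distribution of
RNA Pol II ChIP-seq fragments around transcription start sites. Two windows
are anchored at each gene's TSS, in transcriptional coordinates:

* TSS window: −300 to +300 bp (inclusive, 601 bp), capturing the paused
  polymerase peak;
* downstream window: +301 to +1301 bp (inclusive, 1001 bp), capturing
  early-elongating polymerase.

On the minus strand both windows are mirrored through the TSS. Internally
all windows are 1-based inclusive; BED input/output is 0-based half-open
and the conversion is centralised in the readers/writers, which removes
the classic off-by-one at the TSS. A fragment contributes to every window
it overlaps by at least 1 bp, so a fragment spanning the +300/+301 boundary
counts in both windows — the usual region-count semantics of window
quantification. (5′-end assignment would be the alternative; any-overlap is
the default because fragment length then cancels between conditions.)

Densities are `count / width / (library_size / 10⁶)` and the pause release
ratio is the density ratio

$$\mathrm{PRR} = d_{\mathrm{TSS}} / d_{\mathrm{downstream}}.$$

Because both windows share the library-size factor, PRR is invariant to
sequencing depth and to any per-sample rescaling — which is why no
between-sample normalisation stage exists: it would cancel. Spike-in or
composition normalisation would matter only for comparing absolute
occupancies, which the package deliberately does not do.

## Occupancy selection

Only genes with appreciable Pol II signal carry information about pausing;
for the rest the PRR is a ratio of noise. Across genes, log10 mean control
TSS densities are bimodal — an occupied mode over a background mode — and
are modelled as a two-component Gaussian mixture fitted by EM. The retained
set is every gene whose statistic lies strictly above the
$1-\alpha$ quantile of the fitted lower component, with type-I error
$\alpha = 0.10$ by default: the cutoff is the point beyond which at most
10% of background genes are expected to fall.

Numerical choices, all deterministic:

* initialisation at the 25th/75th percentiles with equal weights and both
  SDs at half the sample SD — no random restarts, so fits are reproducible
  and order-invariant;
* convergence when the log-likelihood improves by less than 1e−8, cap at
  1000 iterations;
* components relabelled so $\mu_{low} < \mu_{high}$ before the cutoff is
  derived, making the fit invariant to label swaps;
* a component weight below 1e−3 or an SD below 1e−6 aborts with an error
  rather than returning a silently degenerate cutoff — this is what
  unimodal input looks like to the fitter;
* genes with zero mean TSS density are dropped (with a log message) before
  the log transform; ties exactly at the cutoff are excluded (strict
  inequality), so the retained set is unambiguous.

The Gaussian-on-log10 family is the canonical choice for this kind of
cutoff; the analytic check that the machinery is right is that a lower
component that is exactly N(0,1) yields a cutoff of $z_{0.90} = 1.2816$ at
$\alpha = 0.10$, which the test suite verifies by simulation (5000 points
from 0.5·N(0,1)+0.5·N(4,1), 20 seeds, tolerance ±0.15) and by cross-check
against an independent mixture fitter (mclust).

## Per-gene and genome-wide statistics

Per gene, replicate PRRs (3 vs 3 by default) are compared between two
conditions with a two-tailed t-test on log10 PRRs, pooled variance by
default. Log10 first: ratio statistics are heavy-tailed and
multiplicative, and the log makes the replicate noise approximately
symmetric; a raw-PRR mode (`log_transform = FALSE`) and a Welch mode
(`var_equal = FALSE`) exist for sensitivity analysis. P-values are BH
adjusted across all tested genes and calls use adjusted p < 0.1, with the
direction from the sign of the replicate-mean log10 PRR difference.

Degenerate cases are resolved explicitly rather than left to NaN:

* zero variance in both groups with equal means: t = 0, p = 1, unchanged;
* zero pooled variance with unequal means (exact separation): the p-value
  is the smallest attainable two-sided permutation p, $2/\binom{n_1+n_2}{n_1}$
  (0.1 for 3 vs 3), and the gene is flagged `exact_separation` — any finite
  parametric p here would be an artefact of a zero variance estimate;
* genes with a zero count in either window of any replicate are excluded
  from the PRR table (logged), because their PRR or its log is undefined;
  a pseudocount mode (+0.5 fragments to both windows) keeps them at the
  cost of a small shrinkage toward 1.

The genome-wide contrast statistic is a paired two-tailed one-sample t-test
on per-gene differences of log10 mean PRRs. "Paired" is the operative word:
the pairing is by gene, which is the only construction under which a
genome-wide pausing comparison between conditions is meaningful, and the
test is named `paired_t` in all outputs. Summaries also report the median
PRR per condition, significant counts per direction, the fraction of genes
below the control median, and ECDFs evaluated on a shared log-spaced grid
(so curves from different conditions are directly overlayable).

## Rescue sets

The rescue question is directional: did the inhibitor push a gene's
expression back against the knockdown's push? A gene is rescued-down when
it is significantly down in knockdown-vs-control (adjusted p < 0.05, the
threshold used for the DE sets) and significantly up in inhibitor-vs-vehicle
(adjusted p < 0.1, the rescue threshold); rescued-up is the mirror image.
Both thresholds are arguments, since the DE-set threshold is a property of
the upstream DE analysis, not of the rescue logic. Genes present in only
one table are treated as not significant in the missing one, and missing
adjusted p-values never reach significance — the conservative readings.
The 4-set Venn partition (2⁴ mutually exclusive regions summing to the
union) is computed exhaustively. DE estimation itself is out of scope: the
module consumes result tables (gene, log2 fold change, adjusted p) from any
DESeq2-style tool.

## What the simulator emulates — and what it does not

The generator exists so that every downstream stage is exercised against
known truth. It emulates, with one knob each:

* **bimodal TSS occupancy**: a fraction `frac_occupied` (default 0.7) of
  genes carry real signal; the rest draw both windows from a background
  rate two decades below the occupied TSS mode (`background_logmean
  = log 0.004` per bp against an occupied-mode median of ≈ 0.5 per bp), so
  the two modes of log TSS density are separated by well over two pooled
  SDs and the mixture cutoff is well-posed;
* **pausing**: per-gene pausing factors are lognormal with median 3.34
  (`pause_logmedian = log 3.34`, spread 0.5) — the calibration centre for
  the control condition — multiplying the TSS window rate only;
* **replicate noise**: negative-binomial counts with dispersion 0.02
  (Poisson in the limit), three replicates per condition, per-bp body rate
  lognormal(log 0.15, 0.5). These defaults were fixed a priori by a power
  calculation: at a uniform 2-fold pausing attenuation they give per-gene
  log10-PRR replicate SDs near 0.1, hence 3v3 pooled-t noncentrality ≈ 3.8
  and comfortably more than 80% of occupied genes called at FDR 0.1, while
  keeping per-sample totals in the low millions — a realistic depth for an
  embryo ChIP triplicate;
* **condition effects** (paired by construction — all conditions share the
  same latent gene parameters): the knockdown multiplies each gene's
  pausing factor by lognormal(log 0.4, 0.25) — a strong, slightly
  heterogeneous attenuation — and the inhibitor-treated knockdown by
  lognormal(log 0.65, 0.40): a partial restoration whose larger spread
  means a minority of genes still move down, reproducing the observed
  asymmetry in which ~90% of significant inhibitor-induced PRR changes are
  increases. No published effect-size distribution exists for either
  condition, so these are declared free parameters of the generator, not
  claims about the biology;
* **DE tables**: observed log2 fold changes are true effects plus Gaussian
  noise with known SE and p-values from the corresponding z-model, BH
  adjusted. This is intentionally not a count model — DE fitting is out of
  scope, and the z-model is the simplest construction whose null p-values
  are exactly uniform, which is what the rescue logic's FDR behaviour
  depends on. One consequence worth knowing: even at tiny SE, true-null
  genes keep uniform p-values, so "noise → 0" sharpens effect genes but
  never sterilises the null — recovery tests therefore check containment
  plus a small false-positive allowance rather than set equality;
* **fragment emission**: fixed-length fragments (default 100 bp) placed
  uniformly and wholly inside their source window, plus optional uniform
  genome-wide background. Full containment makes the
  simulator-to-quantifier round trip exact for foreground fragments, which
  turns conservation into a sharp test: re-quantified counts equal the
  draws exactly with no background, and dominate them otherwise.

Genes are laid out one per 4 kb slot alternating between two synthetic
chromosomes, with random strand and a ±200 bp TSS jitter; windows of
different genes therefore never overlap and each gene's transcribed extent
(1500 bp) always contains the downstream window.

It does **not** emulate: mappability or GC bias, duplicate reads, fragment
length variation, correlated occupancy and expression, multi-TSS isoforms,
chromatin contamination, or batch effects. Passing tests on this generator
therefore demonstrate the statistical machinery — selection behaviour, FDR
control, effect recovery, directionality, determinism — not robustness to
the artefacts of real ChIP-seq, which must be handled upstream (alignment,
filtering, deduplication are all out of scope here).

## Problem sizes and determinism

The test suite runs the full machinery at the sizes where its guarantees
are stated: mixture recovery at 5000 points over 20 seeds; FDR control on
null simulations of 5000 genes, 3v3, over 20 seeds (significant fraction
≤ 0.12 at BH 0.1); parameter recovery at 4000 genes (median PRR ratio
within ±10% of a uniform 0.5× attenuation); overlap counting against an
exhaustive O(n·m) enumeration on 100 random instances; and end-to-end
byte-identity of two pipeline runs at 1000 genes. Every stochastic stage
derives its RNG stream deterministically from the configuration seed (a
distinct fixed offset per stage and condition), so any artifact — counts,
fragment BEDs, DE tables, JSON summaries — is bit-identical across reruns
with the same configuration, and stages can be re-run independently without
disturbing one another's draws.

## Known limitations

* The per-gene t-test treats replicates as exchangeable and gains no
  strength across genes; with 3v3 replicates its power profile is the
  analysis's binding constraint, and shrinkage-based variants (limma-style)
  would be the natural extension.
* The occupancy cutoff assumes two Gaussian components on the log scale;
  heavy contamination between modes, or count discreteness at very low
  background depth, will bias the lower-component SD and hence the cutoff.
* First annotated TSS per gene id is used; genes with alternative promoters
  are summarised by whichever TSS the annotation lists first.
* The rescue logic inherits whatever multiple-testing behaviour the
  upstream DE tool had; it adds no correction of its own beyond consuming
  adjusted p-values.
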
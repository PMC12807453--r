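#' Simulation configuration for synthetic pausing data
#'
#' Builds and validates the parameter set for the bundled data generator. The
#' generator emulates the statistical structure a promoter-proximal pausing
#' analysis assumes: a bimodal distribution of log TSS read densities
#' (Pol II-occupied genes vs. background), lognormal per-gene pausing factors
#' with a control median of 3.34, negative-binomial replicate counts, and
#' condition effects that attenuate pausing (e.g. in a morphant) or partially
#' restore it (e.g. under CDK9 inhibition).
#'
#' Rates are fragments per bp per replicate at nominal depth. The per-gene
#' expected TSS-window count for an occupied gene is
#' `body_rate * pausing_factor * condition_effect * tss_width`, the expected
#' downstream ("body") window count is `body_rate * body_width`; unoccupied
#' genes draw both windows from the background rate. Counts are
#' negative-binomial with dispersion `nb_dispersion` (Poisson in the limit
#' `nb_dispersion -> 0`).
#'
#' @param n_genes number of genes to simulate.
#' @param frac_occupied fraction of genes with real Pol II TSS signal, in (0,1].
#' @param body_rate_logmean,body_rate_logsd lognormal parameters (natural log)
#'   of the per-bp gene-body fragment rate.
#' @param pause_logmedian natural log of the median pausing factor
#'   (default `log(3.34)`, the control median PRR the generator is calibrated
#'   to).
#' @param pause_logsd lognormal spread of per-gene pausing factors.
#' @param background_logmean,background_logsd lognormal parameters of the
#'   per-bp background rate of unoccupied genes; the default puts the lower
#'   mode of log TSS densities about two decades below the upper mode.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param n_replicates replicates per condition (default 3).
#' @param depth_per_sample if non-NULL, rates are rescaled so the expected
#'   total fragment count per sample equals this value.
#' @param condition_effects named list mapping condition label to
#'   `c(logmean=, logsd=)` of the multiplicative per-gene pausing-factor
#'   effect relative to control. Must contain `"control"` (effect 1).
#' @param de_frac_down,de_frac_up fractions of genes with true down/up
#'   expression changes in the morphant contrast.
#' @param de_frac_rescued_down,de_frac_rescued_up fractions of the true
#'   down-/up-regulated genes whose expression change is reversed under the
#'   inhibitor contrast.
#' @param de_se standard error of the observed log2 fold changes in the
#'   simulated DE tables.
#' @param emit_mode `"counts"` (window-count tables) or `"fragments"`
#'   (per-sample BED6 fragment files).
#' @param fragment_length fixed fragment length in bp for fragment emission.
#' @param background_fragments number of genome-wide uniform background
#'   fragments added per emitted sample.
#' @param chrom_length optional chromosome length in bp; by default sized to
#'   fit `n_genes` across two synthetic chromosomes.
#' @param seed integer seed; identical configurations yield bit-identical
#'   outputs.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       frac_occupied = 0.7,
                       body_rate_logmean = log(0.15),
                       body_rate_logsd = 0.5,
                       pause_logmedian = log(3.34),
                       pause_logsd = 0.5,
                       background_logmean = log(0.004),
                       background_logsd = 0.9,
                       nb_dispersion = 0.02,
                       n_replicates = 3,
                       depth_per_sample = NULL,
                       condition_effects = list(
                         control = c(logmean = 0, logsd = 0),
                         morphant = c(logmean = log(0.4), logsd = 0.25),
                         morphant_flavopiridol = c(logmean = log(0.65), logsd = 0.4)),
                       de_frac_down = 0.3,
                       de_frac_up = 0.3,
                       de_frac_rescued_down = 0.25,
                       de_frac_rescued_up = 0.10,
                       de_se = 0.25,
                       emit_mode = c("counts", "fragments"),
                       fragment_length = 100,
                       background_fragments = 0,
                       chrom_length = NULL,
                       seed = 1) {
  emit_mode <- match.arg(emit_mode)
  cfg <- list(n_genes = as.integer(n_genes), frac_occupied = frac_occupied,
              body_rate_logmean = body_rate_logmean,
              body_rate_logsd = body_rate_logsd,
              pause_logmedian = pause_logmedian, pause_logsd = pause_logsd,
              background_logmean = background_logmean,
              background_logsd = background_logsd,
              nb_dispersion = nb_dispersion,
              n_replicates = as.integer(n_replicates),
              depth_per_sample = depth_per_sample,
              condition_effects = condition_effects,
              de_frac_down = de_frac_down, de_frac_up = de_frac_up,
              de_frac_rescued_down = de_frac_rescued_down,
              de_frac_rescued_up = de_frac_rescued_up,
              de_se = de_se, emit_mode = emit_mode,
              fragment_length = as.integer(fragment_length),
              background_fragments = as.integer(background_fragments),
              chrom_length = chrom_length, seed = as.integer(seed))

  if (cfg$n_genes < 0) stop("n_genes must be >= 0")
  if (!(cfg$frac_occupied > 0 && cfg$frac_occupied <= 1))
    stop("frac_occupied must lie in (0, 1]")
  for (f in c("body_rate_logsd", "pause_logsd", "background_logsd", "de_se"))
    if (cfg[[f]] < 0) stop(f, " must be non-negative")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be non-negative")
  if (cfg$n_replicates < 1) stop("n_replicates must be >= 1")
  if (!is.null(cfg$depth_per_sample) && cfg$depth_per_sample <= 0)
    stop("depth_per_sample must be strictly positive")
  if (cfg$fragment_length < 1) stop("fragment_length must be >= 1 bp")
  if (cfg$background_fragments < 0) stop("background_fragments must be >= 0")
  if (cfg$de_frac_down + cfg$de_frac_up > 1)
    stop("de_frac_down + de_frac_up must not exceed 1")
  for (f in c("de_frac_down", "de_frac_up", "de_frac_rescued_down",
              "de_frac_rescued_up"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (is.null(names(cfg$condition_effects)) ||
      !"control" %in% names(cfg$condition_effects))
    stop("condition_effects must be a named list containing 'control'")
  for (nm in names(cfg$condition_effects)) {
    e <- cfg$condition_effects[[nm]]
    if (!all(c("logmean", "logsd") %in% names(e)))
      stop("condition effect '", nm, "' needs logmean and logsd entries")
    if (e[["logsd"]] < 0) stop("condition effect '", nm, "' has negative logsd")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Negative-binomial draw with a Poisson limit at zero dispersion.
rnb_counts <- function(n, mu, dispersion) {
  x <- if (dispersion < 1e-8) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  as.integer(x)
}

# Deterministic sub-stream seed; keeps derived seeds inside 32-bit range.
substream_seed <- function(seed, offset) {
  (abs(as.integer(seed)) + as.integer(offset)) %% 2147483647L
}

# Fixed layout: one gene per 4 kb slot, alternating between two synthetic
# chromosomes, so no two genes' TSS/body windows can overlap.
.SLOT_BP <- 4000L

#' Simulate gene annotations and latent ground truth
#'
#' Places `n_genes` non-overlapping genes on two synthetic chromosomes (random
#' strand, jittered TSS within a private 4 kb slot, transcribed extent 1500 bp
#' so the downstream window always fits) and draws the per-gene latent
#' parameters every downstream stage needs: occupancy flag, body fragment
#' rate, pausing factor, per-condition pausing effects, and true expression
#' effects for the DE/rescue contrasts.
#'
#' @param config a [sim_config()].
#' @return list with `annotations` (data.frame: gene_id, chrom, strand, tss,
#'   gene_end; `chrom_lengths` attribute) and `truth` (one row per gene with
#'   latent parameters, true pausing directions per non-control condition, and
#'   the expression-rescue flag).
#' @export
simulate_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  chroms <- c("chrS1", "chrS2")
  slots_per_chrom <- max(1L, ceiling(n / length(chroms)))
  min_len <- slots_per_chrom * .SLOT_BP + 2000L
  if (is.null(config$chrom_length)) {
    chrom_length <- min_len
  } else {
    chrom_length <- as.integer(config$chrom_length)
    if (length(chroms) * (chrom_length %/% .SLOT_BP) < n)
      stop("chromosome length ", chrom_length, " bp too short to place ",
           n, " genes (need ", .SLOT_BP, " bp per gene across ",
           length(chroms), " chromosomes)")
  }
  chrom_lengths <- stats::setNames(rep(chrom_length, length(chroms)), chroms)

  set.seed(substream_seed(config$seed, 11L))
  if (n == 0L) {
    ann <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), tss = integer(),
                      gene_end = integer(), stringsAsFactors = FALSE)
    attr(ann, "chrom_lengths") <- chrom_lengths
    truth <- data.frame(gene_id = character(), stringsAsFactors = FALSE)
    return(list(annotations = ann, truth = truth))
  }

  idx <- seq_len(n)
  chrom <- chroms[((idx - 1L) %% length(chroms)) + 1L]
  slot <- (idx - 1L) %/% length(chroms)          # slot index within chromosome
  slot_start <- slot * .SLOT_BP                  # 0-based slot origin
  strand <- sample(c("+", "-"), n, replace = TRUE)
  jitter <- sample.int(401L, n, replace = TRUE) - 201L   # [-200, 200]
  tss <- ifelse(strand == "+", slot_start + 1000L, slot_start + 3000L) + jitter
  gene_end <- ifelse(strand == "+", tss + 1500L, tss - 1500L)

  ann <- data.frame(gene_id = sprintf("gene%05d", idx), chrom = chrom,
                    strand = strand, tss = as.integer(tss),
                    gene_end = as.integer(gene_end), stringsAsFactors = FALSE)
  attr(ann, "chrom_lengths") <- chrom_lengths

  occupied <- stats::runif(n) < config$frac_occupied
  body_rate <- stats::rlnorm(n, config$body_rate_logmean, config$body_rate_logsd)
  bg_rate <- stats::rlnorm(n, config$background_logmean, config$background_logsd)
  pause_factor <- stats::rlnorm(n, config$pause_logmedian, config$pause_logsd)

  truth <- data.frame(gene_id = ann$gene_id, occupied = occupied,
                      body_rate = body_rate, bg_rate = bg_rate,
                      pause_factor = pause_factor, stringsAsFactors = FALSE)
  for (cond in names(config$condition_effects)) {
    e <- config$condition_effects[[cond]]
    eff <- exp(stats::rnorm(n, e[["logmean"]], e[["logsd"]]))
    truth[[paste0("effect_", cond)]] <- eff
    if (cond != "control") {
      truth[[paste0("true_direction_", cond)]] <-
        ifelse(eff < 1, "decreased", ifelse(eff > 1, "increased", "unchanged"))
    }
  }

  # True expression effects feeding the DE tables and the rescue contrast.
  u <- stats::runif(n)
  de_class <- ifelse(u < config$de_frac_down, "down",
                     ifelse(u < config$de_frac_down + config$de_frac_up,
                            "up", "none"))
  mag <- 0.5 + abs(stats::rnorm(n))
  lfc_m <- ifelse(de_class == "down", -mag, ifelse(de_class == "up", mag, 0))
  rescued <- (de_class == "down" & stats::runif(n) < config$de_frac_rescued_down) |
             (de_class == "up"   & stats::runif(n) < config$de_frac_rescued_up)
  lfc_f <- ifelse(rescued, -lfc_m * stats::runif(n, 0.5, 1), 0)
  truth$de_lfc_morphant <- lfc_m
  truth$de_lfc_flavopiridol <- lfc_f
  truth$de_rescued <- rescued

  list(annotations = ann, truth = truth)
}

# Expected per-window counts for one condition (before depth rescaling).
.expected_window_means <- function(config, truth, condition, widths) {
  eff <- truth[[paste0("effect_", condition)]]
  if (is.null(eff)) stop("unknown condition label: ", condition,
                         " (not a key of condition_effects)")
  tss_rate <- ifelse(truth$occupied, truth$body_rate * truth$pause_factor * eff,
                     truth$bg_rate)
  body_rate <- ifelse(truth$occupied, truth$body_rate, truth$bg_rate)
  list(tss = tss_rate * widths[["tss"]], body = body_rate * widths[["body"]])
}

#' Simulate replicate window counts for one condition
#'
#' Draws negative-binomial TSS- and body-window counts for every gene and
#' replicate of a condition, sharing the gene-level latent parameters across
#' conditions (paired design). Densities follow the quantification convention:
#' fragments per bp per million mapped fragments, with the library size taken
#' as the sample's total window count.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` data.frame from [simulate_genes()].
#' @param condition a key of `config$condition_effects`.
#' @param spec window geometry, a [window_spec()]; only the widths are used.
#' @return long data.frame: gene_id, condition, replicate, tss_count,
#'   body_count, library_size, tss_density, body_density.
#' @export
simulate_condition_counts <- function(config, truth, condition,
                                      spec = window_spec()) {
  stopifnot(inherits(config, "sim_config"))
  cond_idx <- match(condition, names(config$condition_effects))
  if (is.na(cond_idx)) stop("unknown condition label: ", condition,
                            " (not a key of condition_effects)")
  widths <- c(tss = tss_window_width(spec), body = body_window_width(spec))
  mu <- .expected_window_means(config, truth, condition, widths)
  depth_factor <- 1
  if (!is.null(config$depth_per_sample)) {
    expected_total <- sum(mu$tss) + sum(mu$body)
    if (expected_total > 0) depth_factor <- config$depth_per_sample / expected_total
  }
  n <- nrow(truth)
  set.seed(substream_seed(config$seed, 1000L + 7919L * cond_idx))
  out <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    tss_count <- rnb_counts(n, mu$tss * depth_factor, config$nb_dispersion)
    body_count <- rnb_counts(n, mu$body * depth_factor, config$nb_dispersion)
    lib <- sum(tss_count) + sum(body_count)
    out[[r]] <- data.frame(gene_id = truth$gene_id, condition = condition,
                           replicate = r, tss_count = tss_count,
                           body_count = body_count, library_size = lib,
                           stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, out)
  counts$tss_density <- window_density(counts$tss_count, widths[["tss"]],
                                       counts$library_size)
  counts$body_density <- window_density(counts$body_count, widths[["body"]],
                                        counts$library_size)
  counts
}

#' Simulate the full count table across all configured conditions
#'
#' @inheritParams simulate_condition_counts
#' @return long data.frame combining [simulate_condition_counts()] for every
#'   key of `config$condition_effects`.
#' @export
simulate_counts_table <- function(config, truth, spec = window_spec()) {
  do.call(rbind, lapply(names(config$condition_effects), function(cond)
    simulate_condition_counts(config, truth, cond, spec)))
}

#' Write per-sample BED6 fragment files realising drawn window counts
#'
#' For each sample (condition x replicate) in `counts`, writes exactly the
#' drawn number of fixed-length fragments per window, with start positions
#' uniform inside the window so every foreground fragment is wholly contained
#' in its source window (re-quantification recovers the drawn counts exactly
#' when there is no background), plus `config$background_fragments`
#' genome-wide uniform background fragments.
#'
#' @param counts long count table from [simulate_condition_counts()] or
#'   [simulate_counts_table()].
#' @param annotations annotations from [simulate_genes()] (must carry the
#'   `chrom_lengths` attribute for background placement).
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param spec window geometry used when the counts were drawn.
#' @return named character vector of written file paths
#'   (`<condition>_rep<r>.bed`), names `<condition>.<r>`.
#' @export
emit_fragments <- function(counts, annotations, config, dir,
                           spec = window_spec()) {
  stopifnot(inherits(config, "sim_config"))
  w <- make_windows(annotations, spec)
  frag_len <- config$fragment_length
  if (frag_len > tss_window_width(spec) || frag_len > body_window_width(spec))
    stop("fragment_length (", frag_len, " bp) exceeds a window width")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chrom_lengths <- attr(annotations, "chrom_lengths")
  samples <- unique(counts[, c("condition", "replicate")])
  paths <- character(0)
  for (i in seq_len(nrow(samples))) {
    cond <- samples$condition[i]; rep_i <- samples$replicate[i]
    cond_idx <- match(cond, names(config$condition_effects))
    set.seed(substream_seed(config$seed, 20000L + 977L * cond_idx + rep_i))
    sub <- counts[counts$condition == cond & counts$replicate == rep_i, ]
    sub <- merge(sub, w, by = "gene_id", sort = TRUE)
    draw_window <- function(n_frag, win_start, win_end) {
      # 1-based inclusive window; fragment fully contained
      starts <- rep(win_start, n_frag) +
        floor(stats::runif(sum(n_frag)) *
                rep(win_end - win_start - frag_len + 2L, n_frag))
      starts
    }
    tss_starts <- draw_window(sub$tss_count, sub$tss_start, sub$tss_end)
    body_starts <- draw_window(sub$body_count, sub$body_start, sub$body_end)
    chrom <- c(rep(sub$chrom, sub$tss_count), rep(sub$chrom, sub$body_count))
    starts1 <- c(tss_starts, body_starts)
    if (config$background_fragments > 0) {
      if (is.null(chrom_lengths))
        stop("annotations lack chrom_lengths; cannot place background fragments")
      bg_chrom <- sample(names(chrom_lengths), config$background_fragments,
                         replace = TRUE,
                         prob = chrom_lengths / sum(chrom_lengths))
      bg_start <- 1L + floor(stats::runif(config$background_fragments) *
                               (chrom_lengths[bg_chrom] - frag_len))
      chrom <- c(chrom, bg_chrom)
      starts1 <- c(starts1, bg_start)
    }
    o <- order(chrom, starts1)
    bed <- if (length(o) == 0)
      data.frame(chrom = character(), start = integer(), end = integer(),
                 name = character(), score = integer(), strand = character(),
                 stringsAsFactors = FALSE)
    else data.frame(chrom = chrom[o],
                      start = as.integer(starts1[o] - 1L),     # BED 0-based
                      end = as.integer(starts1[o] - 1L + frag_len),
                      name = sprintf("frag%07d", seq_along(o)),
                      score = 0L, strand = ".", stringsAsFactors = FALSE)
    path <- file.path(dir, sprintf("%s_rep%d.bed", cond, rep_i))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths[sprintf("%s.%d", cond, rep_i)] <- path
  }
  paths
}

#' Simulate DESeq2-style differential-expression result tables
#'
#' Generates three DE tables from the latent expression effects in `truth`:
#' the knockdown-vs-control contrast, the inhibitor-vs-vehicle contrast within
#' the knockdown, and a null contrast with no true effects. Observed log2 fold
#' changes are the true effects plus Gaussian noise with known standard error
#' `config$de_se`; p-values come from the corresponding z-model and are
#' BH-adjusted within each table, so genes with zero true effect have uniform
#' p-values.
#'
#' @inheritParams simulate_condition_counts
#' @return named list of data.frames (`morphant_vs_control`,
#'   `flav_vs_dmso_morphant`, `null_contrast`), each with columns gene_id,
#'   log2FoldChange, pvalue, padj.
#' @export
simulate_de_tables <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth$de_lfc_morphant))
    stop("truth does not contain DE effects; run simulate_genes() first")
  set.seed(substream_seed(config$seed, 50021L))
  make_table <- function(true_lfc) {
    lfc <- true_lfc + stats::rnorm(length(true_lfc), 0, config$de_se)
    z <- lfc / config$de_se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(gene_id = truth$gene_id, log2FoldChange = lfc, pvalue = p,
               padj = stats::p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE)
  }
  list(morphant_vs_control = make_table(truth$de_lfc_morphant),
       flav_vs_dmso_morphant = make_table(truth$de_lfc_flavopiridol),
       null_contrast = make_table(rep(0, nrow(truth))))
}

#' Write gene annotations as BED6
#'
#' BED rows span the transcribed extent (0-based half-open) with the score
#' column set to 0 and the annotated strand; the TSS is recovered on reading
#' as the strand-aware 5' end.
#'
#' @param annotations annotations data.frame from [simulate_genes()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(annotations, path) {
  left <- pmin(annotations$tss, annotations$gene_end)
  right <- pmax(annotations$tss, annotations$gene_end)
  bed <- data.frame(chrom = annotations$chrom, start = left - 1L, end = right,
                    name = annotations$gene_id, score = 0L,
                    strand = annotations$strand, stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
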
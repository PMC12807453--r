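#' Configure an end-to-end pausing pipeline run
#'
#' Validates the configuration for [run_pipeline()] before any computation.
#' Input is either a simulation config (`sim`) or real inputs: an annotation
#' BED plus a condition-to-fragment-file map, or a precomputed long count
#' table (TSV with gene_id, condition, replicate, tss/body counts and
#' densities). Exactly one control condition is required and every threshold
#' must lie in (0, 1); referenced paths must exist at configuration time.
#'
#' @param outdir output directory.
#' @param sim optional [sim_config()]; when given, inputs are simulated.
#' @param annotations annotation BED path (fragment input mode).
#' @param samples named list: condition label -> character vector of BED6
#'   fragment files (fragment input mode).
#' @param counts_file precomputed count-table TSV (count input mode).
#' @param de_tables optional named list with `morphant` and `flavopiridol` DE
#'   TSV paths; when absent and `sim` is given, DE tables are simulated.
#' @param spec a [window_spec()].
#' @param control control condition label.
#' @param contrasts non-control condition labels to test against the control;
#'   defaults to every other condition present.
#' @param type1_error occupancy-cutoff type-I error.
#' @param fdr per-gene BH significance threshold.
#' @param alpha_de,alpha_rescue rescue-stage thresholds.
#' @param seed integer seed for every stochastic stage.
#' @param figures also write figure files (requires ggplot2).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, sim = NULL, annotations = NULL,
                            samples = NULL, counts_file = NULL,
                            de_tables = NULL, spec = window_spec(),
                            control = "control", contrasts = NULL,
                            type1_error = 0.1, fdr = 0.1, alpha_de = 0.05,
                            alpha_rescue = 0.1, seed = 1, figures = FALSE) {
  cfg <- list(outdir = outdir, sim = sim, annotations = annotations,
              samples = samples, counts_file = counts_file,
              de_tables = de_tables, spec = spec, control = control,
              contrasts = contrasts, type1_error = type1_error, fdr = fdr,
              alpha_de = alpha_de, alpha_rescue = alpha_rescue,
              seed = as.integer(seed), figures = isTRUE(figures))
  if (is.null(cfg$outdir) || !nzchar(cfg$outdir))
    stop("validation error: outdir is required")
  for (th in c("type1_error", "fdr", "alpha_de", "alpha_rescue"))
    if (!(cfg[[th]] > 0 && cfg[[th]] < 1))
      stop("validation error: ", th, " must lie in (0, 1)")
  has_sim <- !is.null(cfg$sim)
  if (has_sim && !inherits(cfg$sim, "sim_config"))
    stop("validation error: sim must be a sim_config")
  if (!has_sim && is.null(cfg$counts_file) &&
      (is.null(cfg$annotations) || is.null(cfg$samples)))
    stop("validation error: provide sim, counts_file, or annotations+samples")
  if (!is.null(cfg$samples)) {
    if (is.null(names(cfg$samples)))
      stop("validation error: samples must be named by condition")
    if (!cfg$control %in% names(cfg$samples))
      stop("validation error: samples contain no '", cfg$control,
           "' control condition")
    for (f in unlist(cfg$samples)) if (!file.exists(f))
      stop("validation error: missing sample file ", f)
  }
  if (has_sim && !cfg$control %in% names(cfg$sim$condition_effects))
    stop("validation error: simulation has no '", cfg$control,
         "' control condition")
  for (f in c(cfg$annotations, cfg$counts_file, unlist(cfg$de_tables)))
    if (!is.null(f) && !file.exists(f))
      stop("validation error: missing input file ", f)
  if (!inherits(cfg$spec, "window_spec"))
    stop("validation error: spec must be a window_spec")
  class(cfg) <- "pipeline_config"
  cfg
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pausing pipeline
#'
#' Stages, in order: (1) obtain inputs (simulate annotations/counts, or
#' quantify fragment files, or load a count table); (2) select occupied genes
#' by the mixture cutoff on control TSS densities; (3) per-gene PRR tests and
#' genome-wide summaries for every contrast; (4) opposite-direction rescue
#' analysis of the DE tables. All intermediates are written to `outdir` with
#' declared schemas (`counts.tsv`, `mixture_fit.json`, `prr_<contrast>.tsv`,
#' `summary.json`, `ecdf.tsv`, `rescue_summary.json`, `run_report.json`);
#' a rerun with an identical configuration and seed reproduces byte-identical
#' TSV/JSON outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and the run
#'   report.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("config must come from pipeline_config()")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  report <- list(pausekit_version = as.character(utils::packageVersion("pausekit")),
                 seed = config$seed, control = config$control,
                 thresholds = list(type1_error = config$type1_error,
                                   fdr = config$fdr,
                                   alpha_de = config$alpha_de,
                                   alpha_rescue = config$alpha_rescue),
                 stages = list())

  ## Stage 1: inputs -------------------------------------------------------
  truth <- NULL
  de_tables <- NULL
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    gen <- simulate_genes(sim)
    truth <- gen$truth
    if (sim$emit_mode == "fragments") {
      counts0 <- simulate_counts_table(sim, truth, config$spec)
      frag_dir <- file.path(config$outdir, "fragments")
      paths <- emit_fragments(counts0, gen$annotations, sim, frag_dir,
                              config$spec)
      ann_path <- file.path(config$outdir, "annotations.bed")
      write_gene_bed(gen$annotations, ann_path)
      outputs <- c(outputs, ann_path, unname(paths))
      cond <- sub("\\.[0-9]+$", "", names(paths))
      repl <- as.integer(sub("^.*\\.", "", names(paths)))
      counts <- quantify_samples(gen$annotations, config$spec, paths,
                                 conditions = cond, replicates = repl)
    } else {
      counts <- simulate_counts_table(sim, truth, config$spec)
    }
    de_tables <- simulate_de_tables(sim, truth)
    truth_path <- file.path(config$outdir, "ground_truth.tsv")
    .write_tsv(truth, truth_path)
    outputs <- c(outputs, truth_path)
    report$stages$simulate <- list(n_genes = sim$n_genes,
                                   emit_mode = sim$emit_mode)
  } else if (!is.null(config$counts_file)) {
    counts <- utils::read.delim(config$counts_file, stringsAsFactors = FALSE)
    report$stages$load_counts <- list(
      file = config$counts_file,
      md5 = unname(tools::md5sum(config$counts_file)))
  } else {
    files <- unlist(config$samples, use.names = FALSE)
    cond <- rep(names(config$samples), lengths(config$samples))
    repl <- unlist(lapply(config$samples, seq_along), use.names = FALSE)
    counts <- quantify_samples(config$annotations, config$spec, files,
                               conditions = cond, replicates = repl)
    report$stages$quantify <- list(
      n_samples = length(files),
      input_md5 = as.list(tools::md5sum(c(config$annotations, files))))
  }
  if (!"condition" %in% names(counts))
    stop("count table lacks a condition column")
  counts_path <- file.path(config$outdir, "counts.tsv")
  .write_tsv(counts, counts_path)
  outputs <- c(outputs, counts_path)

  ## Stage 2: occupancy selection ------------------------------------------
  sel <- select_occupied_genes(counts, config$control, config$type1_error)
  fit_path <- file.path(config$outdir, "mixture_fit.json")
  .write_json(unclass(sel$fit), fit_path)
  outputs <- c(outputs, fit_path)
  report$stages$occupancy <- sel$report

  ## Stage 3: PRR tests per contrast ---------------------------------------
  contrasts <- config$contrasts
  if (is.null(contrasts))
    contrasts <- setdiff(unique(counts$condition), config$control)
  if (length(contrasts) == 0) stop("no contrast conditions available")
  prr_tab <- build_prr_table(counts, genes = sel$genes)
  records <- list(); summaries <- list()
  for (ct in contrasts) {
    rec <- test_prr_per_gene(prr_tab, config$control, ct,
                             alpha_fdr = config$fdr)
    records[[ct]] <- rec
    summaries[[ct]] <- summarize_contrast(rec)
    p <- file.path(config$outdir, sprintf("prr_%s.tsv", ct))
    .write_tsv(as.data.frame(rec), p)
    outputs <- c(outputs, p)
  }
  ecdf_all <- do.call(rbind, lapply(contrasts, function(ct) {
    e <- summaries[[ct]]$ecdf
    e$contrast <- ct
    e
  }))
  ecdf_path <- file.path(config$outdir, "ecdf.tsv")
  .write_tsv(ecdf_all, ecdf_path)
  summary_path <- file.path(config$outdir, "summary.json")
  .write_json(lapply(summaries, function(s) {
    s <- unclass(s); s$ecdf <- NULL; s
  }), summary_path)
  outputs <- c(outputs, ecdf_path, summary_path)

  ## Stage 4: rescue --------------------------------------------------------
  rescue <- NULL
  if (!is.null(config$de_tables)) {
    mo <- utils::read.delim(config$de_tables$morphant, stringsAsFactors = FALSE)
    fl <- utils::read.delim(config$de_tables$flavopiridol,
                            stringsAsFactors = FALSE)
    rescue <- compute_rescue(mo, fl, config$alpha_de, config$alpha_rescue)
  } else if (!is.null(de_tables)) {
    rescue <- compute_rescue(de_tables$morphant_vs_control,
                             de_tables$flav_vs_dmso_morphant,
                             config$alpha_de, config$alpha_rescue)
  }
  if (!is.null(rescue)) {
    rp <- file.path(config$outdir, "rescue_summary.json")
    .write_json({
      r <- unclass(rescue); r$sets <- NULL; r$rescued <- NULL
      r$venn <- as.list(r$venn); r
    }, rp)
    outputs <- c(outputs, rp)
    for (nm in names(rescue$sets)) {
      p <- file.path(config$outdir, sprintf("genes_%s.txt", nm))
      writeLines(rescue$sets[[nm]], p)
      outputs <- c(outputs, p)
    }
    for (nm in names(rescue$rescued)) {
      p <- file.path(config$outdir, sprintf("genes_rescued_%s.txt", nm))
      writeLines(rescue$rescued[[nm]], p)
      outputs <- c(outputs, p)
    }
    report$stages$rescue <- list(n_rescued_total = rescue$n_rescued_total)
  }

  if (config$figures) {
    fig_paths <- tryCatch(
      write_figures(summaries, records, config$outdir),
      error = function(e) {
        warning("figure writing failed: ", conditionMessage(e))
        character(0)
      })
    outputs <- c(outputs, fig_paths)
  }

  report$outputs <- basename(outputs)
  report_path <- file.path(config$outdir, "run_report.json")
  .write_json(report, report_path)

  invisible(list(counts = counts, selection = sel, prr = prr_tab,
                 records = records, summaries = summaries, rescue = rescue,
                 truth = truth, report = report))
}

#' Write presentation figures for pausing contrasts
#'
#' Purely presentational: a cumulative-frequency (ECDF) overlay of PRR
#' distributions and, per contrast, a log-log dot plot of control vs contrast
#' mean PRRs coloured by significance call. All numbers live in the TSV/JSON
#' outputs; failures here should be downgraded to warnings by callers.
#'
#' @param summaries named list of `prr_contrast_summary` objects.
#' @param records named list of `prr_records` tables (same names).
#' @param dir output directory.
#' @return character vector of written figure paths.
#' @export
write_figures <- function(summaries, records, dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warning("ggplot2 not available; skipping figures")
    return(character(0))
  }
  if (length(summaries) == 0) {
    warning("no contrasts to plot")
    return(character(0))
  }
  paths <- character(0)
  ecdf_all <- do.call(rbind, lapply(names(summaries), function(ct) {
    e <- summaries[[ct]]$ecdf; e$contrast <- ct; e
  }))
  ecdf_all <- ecdf_all[!duplicated(ecdf_all[, c("prr", "condition")]), ]
  p1 <- ggplot2::ggplot(ecdf_all,
                        ggplot2::aes(x = prr, y = cum_frac,
                                     colour = condition)) +
    ggplot2::geom_step() + ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Pause release ratio", y = "Cumulative fraction",
                  colour = NULL) +
    ggplot2::theme_classic()
  f1 <- file.path(dir, "ecdf_prr.pdf")
  ggplot2::ggsave(f1, p1, width = 5, height = 4)
  paths <- c(paths, f1)
  for (ct in names(records)) {
    rec <- records[[ct]]
    p2 <- ggplot2::ggplot(rec,
                          ggplot2::aes(x = mean_prr_control,
                                       y = mean_prr_other,
                                       colour = direction)) +
      ggplot2::geom_point(size = 0.4, alpha = 0.6) +
      ggplot2::geom_abline(linetype = "dashed") +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::scale_colour_manual(values = c(decreased = "#3366cc",
                                              increased = "#cc3333",
                                              unchanged = "grey60")) +
      ggplot2::labs(x = "Control mean PRR", y = paste(ct, "mean PRR")) +
      ggplot2::theme_classic()
    f2 <- file.path(dir, sprintf("prr_scatter_%s.pdf", ct))
    ggplot2::ggsave(f2, p2, width = 5, height = 4)
    paths <- c(paths, f2)
  }
  paths
}
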
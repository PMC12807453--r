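#' Call significantly changed genes from a DE result table
#'
#' A gene is significant in a given direction when its adjusted p-value is
#' below `alpha` and its log2 fold change has the matching sign (strictly
#' negative for `down`, strictly positive for `up`; zero fold change is never
#' significant). Missing adjusted p-values are treated as not significant,
#' mirroring the independent-filtering convention of DE output tables.
#'
#' @param table data.frame with columns gene_id, log2FoldChange, padj (gene_id
#'   unique).
#' @param alpha adjusted-p threshold in (0, 1); 0 yields an empty set.
#' @param direction `"down"` or `"up"`.
#' @return character vector of gene ids.
#' @export
call_significant <- function(table, alpha, direction = c("down", "up")) {
  direction <- match.arg(direction)
  req <- c("gene_id", "log2FoldChange", "padj")
  if (!all(req %in% names(table)))
    stop("DE table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(table$gene_id))
    stop("gene_id not unique within the DE table")
  if (!(alpha >= 0 && alpha < 1)) stop("alpha must lie in [0, 1)")
  sig <- !is.na(table$padj) & table$padj < alpha &
    if (direction == "down") table$log2FoldChange < 0 else
      table$log2FoldChange > 0
  table$gene_id[sig]
}

#' Opposite-direction rescue-set computation over two DE contrasts
#'
#' A gene is "rescued" when the inhibitor treatment causes a significant
#' expression change in the direction opposite to the change caused by the
#' knockdown: rescued-down genes are significantly down in the
#' knockdown-vs-control contrast and significantly up in the
#' inhibitor-vs-vehicle contrast; rescued-up genes are the mirror image.
#' Genes present in only one table are treated as not significant in the
#' missing contrast (conservative set logic).
#'
#' @param morphant_vs_control DE table for the knockdown-vs-control contrast.
#' @param flav_vs_vehicle DE table for the inhibitor-vs-vehicle contrast
#'   within the knockdown.
#' @param alpha_de adjusted-p threshold defining the knockdown DE sets
#'   (default 0.05).
#' @param alpha_rescue adjusted-p threshold for the opposite-direction change
#'   (default 0.1).
#' @return object of class `rescue_result`: counts of the four primary sets,
#'   rescued counts and percentages, per-partition gene lists, and the full
#'   Venn partition from [venn_counts()].
#' @export
compute_rescue <- function(morphant_vs_control, flav_vs_vehicle,
                           alpha_de = 0.05, alpha_rescue = 0.1) {
  if (nrow(morphant_vs_control) == 0 || nrow(flav_vs_vehicle) == 0)
    stop("both DE tables must be non-empty")
  if (length(intersect(morphant_vs_control$gene_id,
                       flav_vs_vehicle$gene_id)) == 0)
    warning("DE tables share no gene ids; rescue sets are empty")
  down_m <- call_significant(morphant_vs_control, alpha_de, "down")
  up_m <- call_significant(morphant_vs_control, alpha_de, "up")
  down_f <- call_significant(flav_vs_vehicle, alpha_rescue, "down")
  up_f <- call_significant(flav_vs_vehicle, alpha_rescue, "up")
  rescued_down <- intersect(down_m, up_f)
  rescued_up <- intersect(up_m, down_f)
  sets <- list(down_morphant = down_m, up_morphant = up_m,
               down_flav = down_f, up_flav = up_f)
  out <- list(
    n_down_morphant = length(down_m), n_up_morphant = length(up_m),
    n_down_flav = length(down_f), n_up_flav = length(up_f),
    n_rescued_down = length(rescued_down),
    n_rescued_up = length(rescued_up),
    n_rescued_total = length(rescued_down) + length(rescued_up),
    pct_rescued_down = if (length(down_m) > 0)
      100 * length(rescued_down) / length(down_m) else NA_real_,
    pct_rescued_up = if (length(up_m) > 0)
      100 * length(rescued_up) / length(up_m) else NA_real_,
    alpha_de = alpha_de, alpha_rescue = alpha_rescue,
    sets = sets,
    rescued = list(down = rescued_down, up = rescued_up),
    venn = venn_counts(sets))
  class(out) <- "rescue_result"
  out
}

#' @export
print.rescue_result <- function(x, ...) {
  cat("Opposite-direction rescue analysis\n")
  cat(sprintf("  knockdown DE sets (padj < %.3g): %d down, %d up\n",
              x$alpha_de, x$n_down_morphant, x$n_up_morphant))
  cat(sprintf("  inhibitor DE sets (padj < %.3g): %d down, %d up\n",
              x$alpha_rescue, x$n_down_flav, x$n_up_flav))
  cat(sprintf("  rescued: %d of %d down (%.1f%%), %d of %d up (%.1f%%), total %d\n",
              x$n_rescued_down, x$n_down_morphant, x$pct_rescued_down,
              x$n_rescued_up, x$n_up_morphant, x$pct_rescued_up,
              x$n_rescued_total))
  invisible(x)
}

#' Exhaustive Venn partition counts for gene sets
#'
#' Tallies every of the 2^k mutually exclusive membership regions over the
#' union of `k` named sets; region counts sum to the union cardinality (the
#' all-outside region is 0 by construction).
#'
#' @param sets named list of character vectors over a shared namespace.
#' @return named integer vector over all 2^k regions; names are the member
#'   set names joined by `&` (`"(none)"` for the empty region).
#' @export
venn_counts <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be a fully named list")
  k <- length(sets)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  if (length(universe) == 0) member <- matrix(logical(0), ncol = k)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  names(combos) <- names(sets)
  region_name <- apply(combos, 1, function(row) {
    inc <- names(sets)[as.logical(row)]
    if (length(inc) == 0) "(none)" else paste(inc, collapse = "&")
  })
  key <- apply(combos, 1, function(row) paste(as.integer(row), collapse = ""))
  obs <- if (length(universe) > 0)
    apply(member, 1, function(row) paste(as.integer(row), collapse = "")) else
      character(0)
  counts <- stats::setNames(as.integer(table(factor(obs, levels = key))),
                            region_name)
  counts
}
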
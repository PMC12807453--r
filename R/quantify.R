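#' Window geometry around the transcription start site
#'
#' Defines the two windows of the pausing analysis in transcriptional
#' coordinates: a TSS window from `-tss_flank_up` to `+tss_flank_down` bp
#' around the TSS (default -300..+300, width 601 bp) and an abutting
#' downstream window from `+body_start_offset` to `+body_end_offset`
#' (default +301..+1301, width 1001 bp). Both windows are 1-based inclusive;
#' `body_start_offset` must equal `tss_flank_down + 1` so the windows abut and
#' never overlap.
#'
#' @param tss_flank_up,tss_flank_down bp upstream/downstream of the TSS
#'   included in the TSS window.
#' @param body_start_offset,body_end_offset downstream-window bounds in bp
#'   relative to the TSS.
#' @return list of class `window_spec`.
#' @export
window_spec <- function(tss_flank_up = 300, tss_flank_down = 300,
                        body_start_offset = 301, body_end_offset = 1301) {
  spec <- list(tss_flank_up = as.integer(tss_flank_up),
               tss_flank_down = as.integer(tss_flank_down),
               body_start_offset = as.integer(body_start_offset),
               body_end_offset = as.integer(body_end_offset))
  if (any(unlist(spec) <= 0)) stop("all window offsets must be positive")
  if (spec$body_start_offset != spec$tss_flank_down + 1L)
    stop("body_start_offset must equal tss_flank_down + 1 (abutting windows)")
  if (spec$body_end_offset <= spec$body_start_offset)
    stop("body_end_offset must exceed body_start_offset")
  class(spec) <- "window_spec"
  spec
}

#' @rdname window_spec
#' @param spec a `window_spec`.
#' @export
tss_window_width <- function(spec = window_spec())
  spec$tss_flank_up + spec$tss_flank_down + 1L

#' @rdname window_spec
#' @export
body_window_width <- function(spec = window_spec())
  spec$body_end_offset - spec$body_start_offset + 1L

#' Fragment density per bp per million mapped fragments
#'
#' @param count fragment count in the window.
#' @param width window width in bp.
#' @param library_size total mapped fragments in the sample; densities are
#'   undefined (NA, with a warning downstream) when 0.
#' @return numeric density vector.
#' @export
window_density <- function(count, width, library_size) {
  d <- count / width / (library_size / 1e6)
  undef <- !(rep_len(library_size, length(d)) > 0)
  d[undef] <- NA_real_
  d
}

#' Construct strand-aware TSS and downstream windows for genes
#'
#' On the plus strand the TSS window is `[tss - tss_flank_up,
#' tss + tss_flank_down]` and the downstream window `[tss + body_start_offset,
#' tss + body_end_offset]`; on the minus strand both are mirrored through the
#' TSS. Intervals are returned in genomic (left <= right) order, 1-based
#' inclusive. Genes whose windows would extend past the chromosome start are
#' excluded with a warning (their ids are recorded in the `excluded`
#' attribute); if every input gene is excluded this is an error.
#'
#' @param genes annotation data.frame with columns gene_id, chrom, strand
#'   (`+`/`-`), tss (1-based).
#' @param spec a [window_spec()].
#' @return data.frame gene_id, chrom, strand, tss, tss_start, tss_end,
#'   body_start, body_end, with attribute `excluded`.
#' @export
make_windows <- function(genes, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  req <- c("gene_id", "chrom", "strand", "tss")
  if (!all(req %in% names(genes)))
    stop("annotations need columns: ", paste(req, collapse = ", "))
  if (nrow(genes) == 0) {
    out <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), tss = integer(),
                      tss_start = integer(), tss_end = integer(),
                      body_start = integer(), body_end = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "excluded") <- character(0)
    return(out)
  }
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for every gene")
  plus <- genes$strand == "+"
  tss <- as.integer(genes$tss)
  tss_start <- ifelse(plus, tss - spec$tss_flank_up, tss - spec$tss_flank_down)
  tss_end <- ifelse(plus, tss + spec$tss_flank_down, tss + spec$tss_flank_up)
  body_start <- ifelse(plus, tss + spec$body_start_offset,
                       tss - spec$body_end_offset)
  body_end <- ifelse(plus, tss + spec$body_end_offset,
                     tss - spec$body_start_offset)
  ok <- tss_start >= 1L & body_start >= 1L
  excluded <- genes$gene_id[!ok]
  if (length(excluded) > 0) {
    if (!any(ok))
      stop("all genes excluded: windows extend past the chromosome start ",
           "(e.g. ", excluded[1], ")")
    warning(length(excluded),
            " gene(s) excluded: windows extend past the chromosome start")
  }
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand, tss = tss,
                    tss_start = as.integer(tss_start),
                    tss_end = as.integer(tss_end),
                    body_start = as.integer(body_start),
                    body_end = as.integer(body_end),
                    stringsAsFactors = FALSE)[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

.fragments_granges <- function(fragments) {
  if (methods::is(fragments, "GRanges")) return(fragments)
  if (is.data.frame(fragments)) {
    if (nrow(fragments) == 0) return(GenomicRanges::GRanges())
    return(GenomicRanges::GRanges(
      seqnames = fragments$chrom,
      ranges = IRanges::IRanges(start = fragments$start, end = fragments$end)))
  }
  stop("fragments must be a GRanges or a data.frame(chrom, start, end)")
}

#' Read a BED6 fragment or annotation file
#'
#' Thin wrappers over [rtracklayer::import()]: BED input is 0-based
#' half-open and is converted to 1-based inclusive GRanges coordinates.
#' Empty files yield an empty GRanges.
#'
#' @param path BED file path.
#' @return `read_fragments_bed`: a GRanges of fragment intervals.
#' @export
read_fragments_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(GenomicRanges::GRanges())
  rtracklayer::import(path, format = "bed")
}

#' @rdname read_fragments_bed
#' @return `read_gene_bed`: an annotation data.frame (gene_id, chrom, strand,
#'   tss, gene_end) with the TSS at the strand-aware 5' end. Only the first
#'   record per gene_id is kept.
#' @export
read_gene_bed <- function(path) {
  gr <- read_fragments_bed(path)
  if (length(gr) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), tss = integer(),
                      gene_end = integer(), stringsAsFactors = FALSE))
  strand <- as.character(BiocGenerics::strand(gr))
  if (!all(strand %in% c("+", "-")))
    stop("annotation BED must carry +/- strands for every gene")
  ids <- if (!is.null(gr$name)) as.character(gr$name) else
    sprintf("gene%05d", seq_along(gr))
  ann <- data.frame(gene_id = ids,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    strand = strand,
                    tss = ifelse(strand == "+", BiocGenerics::start(gr),
                                 BiocGenerics::end(gr)),
                    gene_end = ifelse(strand == "+", BiocGenerics::end(gr),
                                      BiocGenerics::start(gr)),
                    stringsAsFactors = FALSE)
  ann[!duplicated(ann$gene_id), , drop = FALSE]
}

#' Count fragments overlapping TSS and downstream windows for one sample
#'
#' A fragment contributes to every window it overlaps by at least 1 bp, so a
#' fragment spanning the TSS/downstream boundary counts in both windows.
#' Densities follow the [window_density()] convention; `library_size` defaults
#' to the total number of fragments in the sample.
#'
#' @param fragments GRanges or data.frame(chrom, start, end; 1-based
#'   inclusive) of aligned fragment intervals.
#' @param windows window table from [make_windows()].
#' @param spec the [window_spec()] the windows were built with.
#' @param library_size override for the total mapped fragments.
#' @return data.frame gene_id, tss_count, body_count, library_size,
#'   tss_density, body_density.
#' @export
count_fragments <- function(fragments, windows, spec = window_spec(),
                            library_size = NULL) {
  frags <- .fragments_granges(fragments)
  if (is.null(library_size)) library_size <- length(frags)
  if (length(frags) == 0)
    warning("empty fragment set: all counts zero, densities undefined")
  if (nrow(windows) == 0)
    return(data.frame(gene_id = character(), tss_count = integer(),
                      body_count = integer(), library_size = integer(),
                      tss_density = numeric(), body_density = numeric(),
                      stringsAsFactors = FALSE))
  seqs <- unique(c(as.character(GenomicRanges::seqnames(frags)), windows$chrom))
  tss_gr <- GenomicRanges::GRanges(
    seqnames = factor(windows$chrom, levels = seqs),
    ranges = IRanges::IRanges(windows$tss_start, windows$tss_end))
  body_gr <- GenomicRanges::GRanges(
    seqnames = factor(windows$chrom, levels = seqs),
    ranges = IRanges::IRanges(windows$body_start, windows$body_end))
  tss_count <- GenomicRanges::countOverlaps(tss_gr, frags, minoverlap = 1L,
                                            ignore.strand = TRUE)
  body_count <- GenomicRanges::countOverlaps(body_gr, frags, minoverlap = 1L,
                                             ignore.strand = TRUE)
  data.frame(gene_id = windows$gene_id,
             tss_count = as.integer(tss_count),
             body_count = as.integer(body_count),
             library_size = as.integer(library_size),
             tss_density = window_density(tss_count, tss_window_width(spec),
                                          library_size),
             body_density = window_density(body_count, body_window_width(spec),
                                           library_size),
             stringsAsFactors = FALSE)
}

#' Quantify TSS/downstream window counts for a set of samples
#'
#' Builds windows once (so genes failing window construction are excluded
#' identically across samples) and counts every sample's fragments in them.
#'
#' @param annotations annotation data.frame (gene_id, chrom, strand, tss) or a
#'   BED6 path readable by [read_gene_bed()]; gene_id must be unique.
#' @param spec a [window_spec()].
#' @param sample_files character vector of BED6 fragment file paths; names (or
#'   basenames) become the `sample` column.
#' @param conditions,replicates optional vectors (recycled checks applied)
#'   attaching a condition label and replicate index to each sample.
#' @return long data.frame: gene_id, sample, (condition, replicate,)
#'   tss_count, body_count, library_size, tss_density, body_density; excluded
#'   gene ids in the `excluded` attribute.
#' @export
quantify_samples <- function(annotations, spec = window_spec(), sample_files,
                             conditions = NULL, replicates = NULL) {
  if (is.character(annotations) && length(annotations) == 1)
    annotations <- read_gene_bed(annotations)
  if (anyDuplicated(annotations$gene_id))
    stop("gene_id collision in annotations: ",
         annotations$gene_id[duplicated(annotations$gene_id)][1])
  if (length(sample_files) < 1) stop("at least one sample file is required")
  if (!is.null(conditions) && length(conditions) != length(sample_files))
    stop("conditions must have one entry per sample file")
  if (!is.null(replicates) && length(replicates) != length(sample_files))
    stop("replicates must have one entry per sample file")
  sample_names <- names(sample_files)
  if (is.null(sample_names))
    sample_names <- sub("\\.bed$", "", basename(sample_files))
  windows <- make_windows(annotations, spec)
  out <- vector("list", length(sample_files))
  for (i in seq_along(sample_files)) {
    frags <- read_fragments_bed(sample_files[[i]])
    if (length(frags) == 0)
      stop("sample '", sample_names[i], "' has zero mapped fragments")
    cnt <- count_fragments(frags, windows, spec)
    cnt$sample <- rep(sample_names[i], nrow(cnt))
    if (!is.null(conditions)) cnt$condition <- rep(conditions[i], nrow(cnt))
    if (!is.null(replicates)) cnt$replicate <- rep(replicates[i], nrow(cnt))
    out[[i]] <- cnt
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "excluded") <- attr(windows, "excluded")
  res
}
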
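# Shared fixtures: small simulation configs and a brute-force overlap oracle.

tiny_config <- function(n_genes = 200, seed = 42, ...) {
  sim_config(n_genes = n_genes, seed = seed, ...)
}

null_effects <- list(control = c(logmean = 0, logsd = 0),
                     morphant = c(logmean = 0, logsd = 0))

uniform_halving <- list(control = c(logmean = 0, logsd = 0),
                        morphant = c(logmean = log(0.5), logsd = 0))

# Exhaustive O(n*m) interval-overlap counting; 1-based inclusive coordinates.
# Independent of the GenomicRanges-based implementation.
brute_overlap_counts <- function(frags, windows) {
  n <- nrow(windows)
  tss <- integer(n); body <- integer(n)
  for (i in seq_len(n)) {
    same <- frags$chrom == windows$chrom[i]
    tss[i] <- sum(same & frags$start <= windows$tss_end[i] &
                    frags$end >= windows$tss_start[i])
    body[i] <- sum(same & frags$start <= windows$body_end[i] &
                     frags$end >= windows$body_start[i])
  }
  list(tss_count = tss, body_count = body)
}

# Random fragment set over the span of a window table.
random_fragments <- function(windows, n_frags, frag_len = 100) {
  lo <- min(windows$tss_start, windows$body_start)
  hi <- max(windows$tss_end, windows$body_end)
  start <- sample(max(1, lo - 500):(hi + 500), n_frags, replace = TRUE)
  data.frame(chrom = sample(unique(windows$chrom), n_frags, replace = TRUE),
             start = start, end = start + frag_len - 1L,
             stringsAsFactors = FALSE)
}

# Small end-to-end count table + truth for pausing-module tests.
sim_counts_fixture <- function(n_genes = 1500, seed = 42, effects = NULL) {
  cfg <- if (is.null(effects)) sim_config(n_genes = n_genes, seed = seed) else
    sim_config(n_genes = n_genes, seed = seed, condition_effects = effects)
  gen <- simulate_genes(cfg)
  list(config = cfg, genes = gen,
       counts = simulate_counts_table(cfg, gen$truth))
}
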
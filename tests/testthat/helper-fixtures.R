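# Fixture builders used across test files.

# Write handcrafted alignment records as SAM and convert to a sorted,
# indexed BAM. `records` is a data.frame with columns qname, flag, contig,
# pos1 (1-based leftmost), cigar; lengths is the @SQ dictionary.
make_bam <- function(records, lengths, prefix = tempfile("reads")) {
  sam <- paste0(prefix, ".sam")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", names(lengths), "\tLN:", lengths))
  recs <- if (nrow(records)) {
    paste(records$qname, records$flag, records$contig, records$pos1, 60L,
          records$cigar, "*", 0L, 0L, "*", "*", sep = "\t")
  } else character(0)
  writeLines(c(header, recs), sam)
  bam <- suppressMessages(
    Rsamtools::asBam(sam, prefix, overwrite = TRUE, indexDestination = TRUE))
  unlink(sam)
  bam
}

# Build a cpm_track directly from per-contig numeric vectors (test-only
# shortcut past the count/library-size bookkeeping).
fake_cpm <- function(values, replicate_id = "r", condition = "treated") {
  structure(list(replicate_id = replicate_id, condition = condition,
                 cpm = values),
            class = "cpm_track")
}

# A smoothed condition profile whose smoothed track equals `values`
# exactly (w = 1): lets summit criteria be tested on hand-built numbers.
fake_profile <- function(values, condition = "treated") {
  smooth_profile(aggregate_condition(fake_cpm(values, condition = condition),
                                     condition), w = 1L)
}

# Planted-site SITE-seq simulation at the standard study conditions:
# 50-kb genome, 12 sites with expected treated excess 20 reads/replicate,
# 3 treated + 3 mock replicates, Poisson(0.02)/bp background.
standard_siteseq <- function(seed, n_sites = 12L, genome_length = 50000L,
                             excess = 20, background = 0.02) {
  g <- simulate_genome(genome_length, seed = seed)$genome
  sites <- if (n_sites > 0L) {
    pos <- round(seq(1500, genome_length - 1500, length.out = n_sites))
    data.frame(contig = "sim", position = pos, excess = excess)
  } else {
    data.frame(contig = character(0), position = integer(0),
               excess = numeric(0))
  }
  truth <- sim_truth(sites, background_rate = background, seed = seed + 1L)
  sim <- simulate_site_seq(g, truth, out_dir = tempfile("siteseq"))
  list(genome = g, sites = sites, sim = sim)
}
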
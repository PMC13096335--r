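#' Ground truth for a simulated cleavage-mapping experiment
#'
#' Describes the signal structure the 5'-end simulator plants: sharp
#' treated-only 5'-end excess at cut positions over a Poisson background
#' shared by all replicates.
#'
#' @param planted_sites data.frame with columns `contig`, `position`
#'   (0-based) and `excess` (expected extra treated 5'-end count per
#'   replicate at the site); may have zero rows.
#' @param background_rate expected background 5' ends per bp per replicate.
#' @param n_treated,n_mock replicate counts.
#' @param read_length simulated aligned read length in bases.
#' @param seed RNG seed.
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(planted_sites = data.frame(contig = character(0),
                                                 position = integer(0),
                                                 excess = numeric(0)),
                      background_rate = 0.02, n_treated = 3L, n_mock = 3L,
                      read_length = 100L, seed = 1L) {
  stopifnot(all(c("contig", "position", "excess") %in% names(planted_sites)))
  if (background_rate < 0 || any(planted_sites$excess < 0)) {
    stop("rates must be non-negative")
  }
  structure(list(planted_sites = planted_sites,
                 background_rate = background_rate,
                 n_treated = as.integer(n_treated),
                 n_mock = as.integer(n_mock),
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "sim_truth")
}

#' Simulate a random genome with planted motif instances
#'
#' Draws an i.i.d. sequence at the requested GC fraction and plants
#' concrete instances of a degenerate motif (each degenerate code resolved
#' at random) at recorded non-overlapping positions. Deterministic given
#' the seed.
#'
#' @param length genome length in bases; must be at least
#'   `10 * n_planted_motifs * motif length` so placement is feasible.
#' @param gc_fraction GC content of the background sequence (default 0.35,
#'   typical of T-even phage genomes).
#' @param n_planted_motifs number of motif instances to plant (default 0).
#' @param motif an [iupac_motif()] or pattern string (required when
#'   planting).
#' @param seed RNG seed.
#' @param contig_name name of the simulated contig.
#' @param fasta optional path: write the genome as FASTA.
#' @return List with `genome` (a [genome_index()] with sequence) and
#'   `truth` (data.frame of planted `position` and resolved `instance`).
#' @export
simulate_genome <- function(length, gc_fraction = 0.35,
                            n_planted_motifs = 0L, motif = NULL, seed = 1L,
                            contig_name = "sim", fasta = NULL) {
  length <- as.integer(length)
  n_planted_motifs <- as.integer(n_planted_motifs)
  if (n_planted_motifs > 0L) {
    if (is.null(motif)) stop("a motif is required to plant instances")
    if (!inherits(motif, "iupac_motif")) motif <- iupac_motif(motif)
    if (length < 10L * n_planted_motifs * motif$length) {
      stop("genome too short for the requested number of planted motifs")
    }
  }
  res <- with_seed(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    bases <- sample(names(p), length, replace = TRUE, prob = p)
    truth <- data.frame(position = integer(0), instance = character(0),
                        stringsAsFactors = FALSE)
    if (n_planted_motifs > 0L) {
      ml <- motif$length
      placed <- integer(0)
      tries <- 0L
      while (base::length(placed) < n_planted_motifs) {
        tries <- tries + 1L
        if (tries > 1000L * n_planted_motifs) {
          stop("infeasible motif placement")
        }
        pos <- sample.int(length - ml + 1L, 1L) - 1L
        if (any(abs(pos - placed) < ml)) next
        inst <- vapply(strsplit(motif$pattern, "")[[1]], function(code) {
          opts <- strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1]]
          opts[sample.int(base::length(opts), 1L)]
        }, character(1), USE.NAMES = FALSE)
        bases[(pos + 1L):(pos + ml)] <- inst
        placed <- c(placed, pos)
        truth <- rbind(truth, data.frame(position = pos,
                                         instance = paste(inst, collapse = ""),
                                         stringsAsFactors = FALSE))
      }
      truth <- truth[order(truth$position), , drop = FALSE]
    }
    list(seq = paste(bases, collapse = ""), truth = truth)
  })
  dna <- Biostrings::DNAStringSet(res$seq)
  names(dna) <- contig_name
  if (!is.null(fasta)) Biostrings::writeXStringSet(dna, fasta)
  list(genome = genome_index(stats::setNames(length, contig_name),
                             seq = dna),
       truth = res$truth)
}

# Write SAM records and convert to a coordinate-sorted, indexed BAM.
# pos0: 0-based leftmost aligned position; rev: logical strand.
.write_sim_bam <- function(qname, flag, contig, pos0, cigar, prefix,
                           genome) {
  sam <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", names(genome$lengths),
                     "\tLN:", genome$lengths))
  recs <- if (length(qname)) {
    paste(qname, flag, contig, pos0 + 1L, 60L, cigar, "*", 0L, 0L, "*",
          "*", sep = "\t")
  } else character(0)
  writeLines(c(header, recs), sam)
  out <- suppressMessages(
    Rsamtools::asBam(sam, prefix, overwrite = TRUE,
                     indexDestination = TRUE))
  unlink(sam)
  out
}

#' Simulate SITE-seq style alignment files with planted cut sites
#'
#' Per replicate, background reads are placed with 5' ends at uniform
#' random positions on random strands (count ~ Poisson(background_rate x
#' contig length)); treated replicates additionally receive
#' Poisson-distributed reads whose 5' end lies exactly at each planted
#' position (forward strand, or alternating strands with a positional
#' stagger when `stagger` is set). Every record is a primary, mapped,
#' R1-flagged alignment consuming `read_length` reference bases; reads
#' that would extend past the contig end are re-drawn. Deterministic given
#' the truth's seed.
#'
#' @param genome a [genome_index()].
#' @param truth a [sim_truth()].
#' @param out_dir directory for the BAM files (created if needed).
#' @param stagger optional integer: reverse-strand planted reads offset by
#'   this many bases (probes summit merging); default `NULL` = forward
#'   only.
#' @return List with `treated` and `mock` (vectors of BAM paths), `tracks`
#'   (the simulator's internal 5'-end tallies as [end_count_track()]s,
#'   named as the files) and `truth`. A `truth.json` with the planted
#'   sites is written alongside the BAMs.
#' @export
simulate_site_seq <- function(genome, truth, out_dir = tempfile("siteseq"),
                              stagger = NULL) {
  stopifnot(inherits(genome, "genome_index"), inherits(truth, "sim_truth"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  L <- truth$read_length
  bad <- setdiff(unique(truth$planted_sites$contig), names(genome$lengths))
  if (length(bad)) stop("planted contig(s) absent from genome: ",
                        paste(bad, collapse = ", "))
  with_seed(truth$seed, {
    sim_replicate <- function(rep_id, condition, prefix) {
      qname <- character(0); flag <- integer(0); contig <- character(0)
      pos0 <- integer(0)
      tally <- lapply(genome$lengths, function(len) integer(len))
      add <- function(ctg, p5, rev) {
        n <- length(p5)
        if (!n) return()
        # leftmost aligned base of each record
        left <- ifelse(rev, p5 - L + 1L, p5)
        qname <<- c(qname, sprintf("%s_r%06d", rep_id,
                                   length(qname) + seq_len(n)))
        flag <<- c(flag, ifelse(rev, 89L, 73L))  # paired+R1+mate unmapped
        contig <<- c(contig, rep(ctg, n))
        pos0 <<- c(pos0, left)
        tally[[ctg]] <<- tally[[ctg]] + tabulate(p5 + 1L,
                                                 nbins = length(tally[[ctg]]))
      }
      for (ctg in names(genome$lengths)) {
        len <- genome$lengths[[ctg]]
        if (len < L) stop("contig ", ctg, " shorter than read_length")
        n_bg <- rpois(1L, truth$background_rate * len)
        if (n_bg > 0L) {
          rev <- runif(n_bg) < 0.5
          # drawing directly from the in-bounds range is equivalent to
          # redrawing reads that would run off the contig
          p5 <- integer(n_bg)
          p5[!rev] <- sample.int(len - L + 1L, sum(!rev), replace = TRUE) - 1L
          p5[rev] <- sample.int(len - L + 1L, sum(rev), replace = TRUE) +
            L - 2L
          add(ctg, p5[!rev], rep(FALSE, sum(!rev)))
          add(ctg, p5[rev], rep(TRUE, sum(rev)))
        }
      }
      if (condition == "treated" && nrow(truth$planted_sites)) {
        for (i in seq_len(nrow(truth$planted_sites))) {
          site <- truth$planted_sites[i, ]
          n <- rpois(1L, site$excess)
          if (n == 0L) next
          len <- genome$lengths[[site$contig]]
          if (is.null(stagger)) {
            if (site$position + L > len) {
              stop("planted site too close to contig end for read_length")
            }
            add(site$contig, rep(site$position, n), rep(FALSE, n))
          } else {
            rev <- runif(n) < 0.5
            fwd_p <- rep(site$position, sum(!rev))
            rev_p <- rep(min(site$position + stagger, len - 1L), sum(rev))
            add(site$contig, fwd_p, rep(FALSE, sum(!rev)))
            add(site$contig, rev_p, rep(TRUE, sum(rev)))
          }
        }
      }
      bam <- .write_sim_bam(qname, flag, contig, pos0, paste0(L, "M"),
                            prefix, genome)
      list(bam = bam,
           track = end_count_track(tally, rep_id, condition))
    }
    treated <- lapply(seq_len(truth$n_treated), function(i) {
      sim_replicate(paste0("treated_", i), "treated",
                    file.path(out_dir, paste0("treated_", i)))
    })
    mock <- lapply(seq_len(truth$n_mock), function(i) {
      sim_replicate(paste0("mock_", i), "mock",
                    file.path(out_dir, paste0("mock_", i)))
    })
    jsonlite::write_json(
      list(planted_sites = truth$planted_sites,
           background_rate = truth$background_rate,
           n_treated = truth$n_treated, n_mock = truth$n_mock,
           read_length = truth$read_length, seed = truth$seed),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    list(treated = vapply(treated, `[[`, character(1), "bam"),
         mock = vapply(mock, `[[`, character(1), "bam"),
         tracks = c(lapply(treated, `[[`, "track"),
                    lapply(mock, `[[`, "track")),
         truth = truth)
  })
}

#' Simulate genome annotations for the neighborhood analysis
#'
#' Per genome, tRNA genes are placed by a Poisson process at the background
#' rate genome-wide, with additional placements inside the focal gene's
#' +/-`flank` region at `background_rate * (enrichment - 1)` so that the
#' proximal rate is `background_rate * enrichment`. Deterministic given the
#' seed.
#'
#' @param n_genomes number of genomes.
#' @param genome_length_mean,genome_length_sd genome length distribution
#'   (normal, rounded; default 60 kb +/- 15 kb, floored at 10 kb).
#' @param background_rate background tRNA genes per bp (default 1e-4).
#' @param enrichment proximal rate multiplier (default 5; 1 = no effect,
#'   0 = no proximal placements beyond background spillover).
#' @param focal_gene_length focal gene length in bp (default 700).
#' @param flank proximal flank in bp (default 1000).
#' @param trna_length tRNA gene length in bp (default 76).
#' @param seed RNG seed.
#' @return List with `annotations` (list of [genome_annotation()]) and
#'   `config` (the parameters used).
#' @export
simulate_neighborhood <- function(n_genomes, genome_length_mean = 60000,
                                  genome_length_sd = 15000,
                                  background_rate = 1e-4, enrichment = 5,
                                  focal_gene_length = 700L, flank = 1000L,
                                  trna_length = 76L, seed = 1L) {
  if (enrichment < 0) stop("enrichment must be >= 0")
  anns <- with_seed(seed, {
    lapply(seq_len(n_genomes), function(g) {
      len <- max(10000, round(rnorm(1, genome_length_mean, genome_length_sd)))
      gene_start <- sample.int(len - focal_gene_length, 1L) - 1L
      gene <- c(gene_start, gene_start + focal_gene_length)
      place <- function(n, lo, hi) {
        if (n == 0L || hi - lo < trna_length) {
          return(cbind(start = numeric(0), end = numeric(0)))
        }
        s <- lo + sample.int(hi - lo - trna_length + 1L, n,
                             replace = TRUE) - 1L
        cbind(start = s, end = s + trna_length)
      }
      tr <- place(rpois(1L, background_rate * len), 0, len)
      reg_lo <- max(gene[1] - flank, 0)
      reg_hi <- min(gene[2] + flank, len)
      extra_rate <- background_rate * max(enrichment - 1, 0) *
        (reg_hi - reg_lo)
      if (enrichment < 1) {
        # thin background inside the region down to the proximal rate
        inside <- tr[, "start"] >= reg_lo & tr[, "end"] <= reg_hi
        drop <- inside & runif(nrow(tr)) > enrichment
        tr <- tr[!drop, , drop = FALSE]
        extra_rate <- 0
      }
      tr <- rbind(tr, place(rpois(1L, extra_rate), reg_lo, reg_hi))
      tr <- tr[order(tr[, "start"]), , drop = FALSE]
      genome_annotation(sprintf("genome_%04d", g), len, gene, tr)
    })
  })
  list(annotations = anns,
       config = list(n_genomes = n_genomes,
                     genome_length_mean = genome_length_mean,
                     genome_length_sd = genome_length_sd,
                     background_rate = background_rate,
                     enrichment = enrichment,
                     focal_gene_length = focal_gene_length, flank = flank,
                     trna_length = trna_length, seed = seed))
}

#' Simulate a pair of tRF 5'-base coverage vectors
#'
#' Both conditions share a Poisson background; the "with defense" condition
#' receives an additional Poisson spike at the cleavage position.
#' Deterministic given the seed.
#'
#' @param locus_length locus length in nt (default 85, a long tRNA).
#' @param cleavage_position 0-based cleavage position (default 48, the
#'   variable-loop position typical of tRNA-Tyr cleavage).
#' @param spike expected extra 5'-end count at the cleavage position in the
#'   defended condition.
#' @param background expected background count per position.
#' @param seed RNG seed.
#' @param locus locus name.
#' @return List with `with_defense` and `without_defense`
#'   ([trf_coverage()] objects) and `truth` (the parameters).
#' @export
simulate_trf <- function(locus_length = 85L, cleavage_position = 48L,
                         spike = 200, background = 5, seed = 1L,
                         locus = "tRNA-Tyr") {
  if (cleavage_position < 0L || cleavage_position >= locus_length) {
    stop("cleavage_position outside the locus")
  }
  with_seed(seed, {
    wo <- rpois(locus_length, background)
    wi <- rpois(locus_length, background)
    wi[cleavage_position + 1L] <- wi[cleavage_position + 1L] +
      rpois(1L, spike)
    list(with_defense = trf_coverage(wi, locus, "with_defense"),
         without_defense = trf_coverage(wo, locus, "without_defense"),
         truth = list(locus_length = locus_length,
                      cleavage_position = cleavage_position, spike = spike,
                      background = background, seed = seed))
  })
}
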
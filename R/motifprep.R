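#' IUPAC-degenerate nucleotide motif
#'
#' @param pattern string over the IUPAC nucleotide alphabet
#'   (A C G T R Y S W K M B D H V N), e.g. `"RAWTSGAAC"`.
#' @return An object of class `iupac_motif`.
#' @export
iupac_motif <- function(pattern) {
  pattern <- toupper(as.character(pattern))
  chars <- strsplit(pattern, "")[[1]]
  valid <- names(Biostrings::IUPAC_CODE_MAP)
  if (length(chars) == 0L || !all(chars %in% valid)) {
    stop("invalid IUPAC character(s) in motif: ",
         paste(setdiff(chars, valid), collapse = ", "))
  }
  structure(list(pattern = pattern, length = length(chars)),
            class = "iupac_motif")
}

#' Extract fixed-width windows around peak summits
#'
#' One window of `2 * flank + 1` bases centered on each summit; summits
#' whose window would cross a contig boundary are skipped (their number is
#' reported in a message and in attribute `"n_skipped"`).
#'
#' @param peaks peaks data.frame (needs `contig` and `summit` columns) or a
#'   `peak_set`.
#' @param genome a [genome_index()] with sequence access.
#' @param flank half-width in bp (default 20).
#' @return data.frame with columns `contig`, `summit`, `sequence`.
#' @seealso [write_windows_fasta()]
#' @export
extract_windows <- function(peaks, genome, flank = 20L) {
  if (inherits(peaks, "peak_set")) peaks <- peaks$peaks
  stopifnot(inherits(genome, "genome_index"))
  if (is.null(genome$seq)) stop("genome index has no sequence access")
  flank <- as.integer(flank)
  len <- as.integer(genome$lengths[peaks$contig])
  ok <- peaks$summit - flank >= 0L & peaks$summit + flank < len
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    message(n_skipped, " summit window(s) crossed a contig boundary; skipped")
  }
  kept <- peaks[ok, , drop = FALSE]
  seqs <- vapply(seq_len(nrow(kept)), function(i) {
    get_sequence(genome, kept$contig[i], kept$summit[i] - flank,
                 kept$summit[i] + flank + 1L)
  }, character(1))
  out <- data.frame(contig = kept$contig, summit = kept$summit,
                    sequence = seqs, stringsAsFactors = FALSE)
  attr(out, "flank") <- flank
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write summit windows to FASTA
#'
#' Headers encode `contig:summit` so each window can be traced back.
#'
#' @param windows data.frame from [extract_windows()].
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_windows_fasta <- function(windows, file) {
  s <- Biostrings::DNAStringSet(windows$sequence)
  if (length(s)) names(s) <- paste0(windows$contig, ":", windows$summit)
  Biostrings::writeXStringSet(s, file)
  invisible(file)
}

#' Scan a sequence for an IUPAC-degenerate motif
#'
#' A position matches when every motif position's IUPAC set contains the
#' sequence base; `N` in the sequence never matches a non-N motif code.
#' Minus-strand hits are found by scanning the reverse complement and are
#' reported at their plus-strand offsets.
#'
#' @param sequence string over A/C/G/T/N (a concrete sequence, not a
#'   degenerate one).
#' @param motif an [iupac_motif()] or a pattern string.
#' @param both_strands also scan the reverse complement (default `TRUE`).
#' @return data.frame with columns `offset` (0-based plus-strand offset of
#'   the match start) and `strand` (`"+"`/`"-"`), sorted by offset.
#' @export
#' @examples
#' scan_iupac("AATTCGAAC", "RAWTSGAAC")
scan_iupac <- function(sequence, motif, both_strands = TRUE) {
  if (!inherits(motif, "iupac_motif")) motif <- iupac_motif(motif)
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) && !all(chars %in% c("A", "C", "G", "T", "N"))) {
    stop("sequence must be over {A, C, G, T, N}")
  }
  subj <- Biostrings::DNAString(toupper(sequence))
  pat <- Biostrings::DNAString(motif$pattern)
  hit_offsets <- function(s) {
    # fixed = "subject": motif ambiguity codes expand, subject bases are
    # literal, so subject N matches only a motif N
    m <- Biostrings::matchPattern(pat, s, fixed = "subject")
    BiocGenerics::start(m) - 1L
  }
  plus <- hit_offsets(subj)
  out <- data.frame(offset = plus,
                    strand = rep("+", length(plus)),
                    stringsAsFactors = FALSE)
  if (both_strands) {
    rc_hits <- hit_offsets(Biostrings::reverseComplement(subj))
    minus <- length(subj) - rc_hits - motif$length
    out <- rbind(out, data.frame(offset = minus,
                                 strand = rep("-", length(minus)),
                                 stringsAsFactors = FALSE))
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Count motif-bearing summit windows
#'
#' @param windows data.frame from [extract_windows()].
#' @param motif an [iupac_motif()] or pattern string.
#' @param both_strands scan both strands (default `TRUE`).
#' @return Integer count of windows with at least one match; the per-window
#'   logical flags are attached as attribute `"has_motif"`.
#' @export
count_motif_windows <- function(windows, motif, both_strands = TRUE) {
  if (!inherits(motif, "iupac_motif")) motif <- iupac_motif(motif)
  flags <- vapply(windows$sequence, function(s) {
    nrow(scan_iupac(s, motif, both_strands = both_strands)) > 0L
  }, logical(1), USE.NAMES = FALSE)
  structure(sum(flags), has_motif = flags)
}

#' Emit the shell command for external de novo motif discovery
#'
#' Motif discovery itself is delegated to MEME; this records the parameters
#' used alongside the exported window FASTA (ZOOPS mode, up to five motifs,
#' width 5-15, both strands).
#'
#' @param fasta path of the window FASTA.
#' @param out_dir MEME output directory.
#' @return The command string, invisibly printed.
#' @export
meme_command <- function(fasta, out_dir = "meme_out") {
  cmd <- paste("meme", fasta, "-dna -revcomp -mod zoops -nmotifs 5",
               "-minw 5 -maxw 15 -oc", out_dir)
  cat(cmd, "\n")
  invisible(cmd)
}
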
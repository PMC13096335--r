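#' Genome index: contig lengths with optional sequence access
#'
#' A lightweight handle on a reference genome: an ordered set of contig
#' lengths, optionally backed by the sequences themselves so that windows
#' can be extracted. All coordinates in the package are 0-based; intervals
#' are half-open `[start, end)`.
#'
#' @param lengths named integer vector of contig lengths (bases); names are
#'   contig names and must be unique, lengths must be positive.
#' @param seq optional [Biostrings::DNAStringSet] whose names and widths
#'   match `lengths`.
#' @return An object of class `genome_index`.
#' @seealso [read_genome()] to build one from a FASTA file.
#' @export
#' @examples
#' gi <- genome_index(c(chr = 1000L))
#' contig_lengths(gi)
genome_index <- function(lengths, seq = NULL) {
  lengths <- stats::setNames(as.integer(lengths), names(lengths))
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)) ||
      any(!nzchar(names(lengths)))) {
    stop("contig lengths must be uniquely named")
  }
  if (any(lengths <= 0L)) stop("contig lengths must be positive")
  if (!is.null(seq)) {
    if (!methods::is(seq, "DNAStringSet")) {
      stop("'seq' must be a DNAStringSet")
    }
    if (!setequal(names(seq), names(lengths)) ||
        !all(Biostrings::width(seq)[match(names(lengths), names(seq))] ==
             lengths)) {
      stop("sequence names/widths do not match contig lengths")
    }
    seq <- seq[names(lengths)]
  }
  structure(list(lengths = lengths, seq = seq), class = "genome_index")
}

#' Read a reference genome from FASTA
#'
#' @param fasta path to an (uncompressed or gzipped) FASTA file.
#' @param with_sequence keep the sequences for window extraction (default
#'   `TRUE`); set to `FALSE` to hold lengths only.
#' @return A [genome_index()].
#' @export
read_genome <- function(fasta, with_sequence = TRUE) {
  seq <- Biostrings::readDNAStringSet(fasta)
  # FASTA headers may carry descriptions after the first whitespace
  names(seq) <- sub("\\s.*$", "", names(seq))
  lens <- stats::setNames(Biostrings::width(seq), names(seq))
  genome_index(lens, seq = if (with_sequence) seq else NULL)
}

#' @rdname genome_index
#' @param genome a `genome_index`.
#' @export
contig_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_index"))
  genome$lengths
}

#' Extract a genomic subsequence
#'
#' @param genome a [genome_index()] built with sequence access.
#' @param contig contig name.
#' @param start,end 0-based half-open interval.
#' @return Character string of length `end - start`.
#' @export
get_sequence <- function(genome, contig, start, end) {
  stopifnot(inherits(genome, "genome_index"))
  if (is.null(genome$seq)) stop("genome index has no sequence access")
  len <- genome$lengths[[contig]]
  if (is.null(len)) stop("unknown contig: ", contig)
  if (start < 0 || end > len || start >= end) {
    stop("interval [", start, ", ", end, ") outside contig ", contig)
  }
  as.character(Biostrings::subseq(genome$seq[[contig]], start + 1L, end))
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index:", length(x$lengths), "contig(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp",
      if (is.null(x$seq)) "(lengths only)" else "(with sequence)", "\n")
  invisible(x)
}
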
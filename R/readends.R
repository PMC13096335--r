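#' Alignment filter configuration
#'
#' Controls which alignment records contribute 5'-end events. The defaults
#' reproduce the filters used for SITE-seq style cleavage mapping: only
#' first mates (R1), primary mapped non-duplicate records, and a minimum
#' aligned length of 40 bases.
#'
#' @param min_aligned_length minimum aligned length in bases (default 40);
#'   records spanning fewer bases are dropped.
#' @param exclude_flags character vector of record categories to exclude;
#'   any subset of `"unmapped"`, `"secondary"`, `"supplementary"`,
#'   `"duplicate"`, `"qc_fail"` (all excluded by default).
#' @param min_mapping_quality minimum MAPQ (default 0, i.e. no filter).
#' @param r1_only for paired records keep only first mates (default `TRUE`);
#'   unpaired records are always treated as R1.
#' @param aligned_length_space how aligned length is measured:
#'   `"reference"` (reference-consumed span, the default) or `"query"`
#'   (query bases aligned, soft clips excluded).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_aligned_length = 40L,
                          exclude_flags = c("unmapped", "secondary",
                                            "supplementary", "duplicate",
                                            "qc_fail"),
                          min_mapping_quality = 0L,
                          r1_only = TRUE,
                          aligned_length_space = c("reference", "query")) {
  known <- c("unmapped", "secondary", "supplementary", "duplicate", "qc_fail")
  exclude_flags <- as.character(exclude_flags)
  if (!all(exclude_flags %in% known)) {
    stop("unknown flag categories: ",
         paste(setdiff(exclude_flags, known), collapse = ", "))
  }
  min_aligned_length <- as.integer(min_aligned_length)
  min_mapping_quality <- as.integer(min_mapping_quality)
  if (min_aligned_length < 1L) stop("min_aligned_length must be >= 1")
  if (min_mapping_quality < 0L) stop("min_mapping_quality must be >= 0")
  structure(list(min_aligned_length = min_aligned_length,
                 exclude_flags = exclude_flags,
                 min_mapping_quality = min_mapping_quality,
                 r1_only = isTRUE(r1_only),
                 aligned_length_space = match.arg(aligned_length_space)),
            class = "filter_config")
}

# SAM flag bits for the filterable categories
.flag_bits <- c(unmapped = 4L, secondary = 256L, supplementary = 2048L,
                qc_fail = 512L, duplicate = 1024L)

#' Construct a 5'-end count track
#'
#' Usually produced by [extract_r1_ends()] or the simulators; the direct
#' constructor is exposed so tracks can be built in code.
#'
#' @param counts named list of non-negative integer vectors, one per contig,
#'   each of the contig's length (0-based positions).
#' @param replicate_id replicate label.
#' @param condition `"treated"` or `"mock"`.
#' @param library_size total retained 5'-end events; defaults to the sum of
#'   `counts` and must equal it.
#' @return An object of class `end_count_track`.
#' @export
end_count_track <- function(counts, replicate_id, condition,
                            library_size = NULL) {
  condition <- match.arg(condition, c("treated", "mock"))
  if (is.null(names(counts))) stop("'counts' must be a named list of contigs")
  counts <- lapply(counts, function(x) {
    x <- as.integer(x)
    if (any(x < 0L)) stop("counts must be non-negative")
    x
  })
  total <- sum(vapply(counts, function(x) sum(as.numeric(x)), numeric(1)))
  if (is.null(library_size)) library_size <- total
  if (library_size != total) {
    stop("library_size (", library_size, ") != total counts (", total, ")")
  }
  structure(list(replicate_id = as.character(replicate_id),
                 condition = condition, counts = counts,
                 library_size = as.numeric(library_size)),
            class = "end_count_track")
}

#' @export
print.end_count_track <- function(x, ...) {
  cat("end_count_track '", x$replicate_id, "' (", x$condition, "): ",
      length(x$counts), " contig(s), library size ",
      format(x$library_size, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Reduce an alignment file to per-base R1 5'-end counts
#'
#' Parses a coordinate-sorted, indexed BAM file, applies the mapping filters
#' in `cfg`, and increments one count per retained record at its 5'-end
#' reference position: the leftmost aligned base for forward-strand records,
#' the rightmost aligned base for reverse-strand records (0-based). Both
#' strands accumulate into a single array per contig.
#'
#' @param file path to a coordinate-sorted BAM with a `.bai` index, or a
#'   [Rsamtools::BamFile].
#' @param genome a [genome_index()]; contigs seen in the alignments must be
#'   present with matching lengths.
#' @param replicate_id replicate label recorded on the track.
#' @param condition `"treated"` or `"mock"`.
#' @param cfg a [filter_config()].
#' @param per_strand also return forward/reverse tracks separately in
#'   attribute `"per_strand"` (default `FALSE`).
#' @return An [end_count_track()]; `library_size` equals the number of
#'   retained records.
#' @export
extract_r1_ends <- function(file, genome, replicate_id,
                            condition = c("treated", "mock"),
                            cfg = filter_config(), per_strand = FALSE) {
  condition <- match.arg(condition)
  stopifnot(inherits(genome, "genome_index"), inherits(cfg, "filter_config"))
  if (is.character(file)) {
    if (!file.exists(file)) stop("no such alignment file: ", file)
    idx <- paste0(file, ".bai")
    if (!file.exists(idx) && !file.exists(sub("\\.bam$", ".bai", file))) {
      stop("missing BAM index (.bai) for ", file)
    }
    bf <- Rsamtools::BamFile(file)
  } else {
    bf <- file
  }
  res <- Rsamtools::scanBam(
    bf,
    param = Rsamtools::ScanBamParam(
      what = c("flag", "rname", "strand", "pos", "cigar", "mapq")))[[1]]

  flag <- res$flag
  keep <- rep(TRUE, length(flag))
  for (cat in cfg$exclude_flags) {
    keep <- keep & bitwAnd(flag, .flag_bits[[cat]]) == 0L
  }
  if (cfg$r1_only) {
    paired <- bitwAnd(flag, 1L) != 0L
    first <- bitwAnd(flag, 64L) != 0L
    keep <- keep & (!paired | first)  # unpaired records count as R1
  }
  keep <- keep & !is.na(res$pos)
  if (cfg$min_mapping_quality > 0L) {
    keep <- keep & !is.na(res$mapq) & res$mapq >= cfg$min_mapping_quality
  }
  cigar <- res$cigar
  alen <- rep(NA_integer_, length(flag))
  ok <- keep & !is.na(cigar)
  if (any(ok)) {
    alen[ok] <- if (cfg$aligned_length_space == "reference") {
      GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[ok])
    } else {
      GenomicAlignments::cigarWidthAlongQuerySpace(cigar[ok],
                                                   after.soft.clipping = TRUE)
    }
  }
  keep <- ok & alen >= cfg$min_aligned_length

  rname <- as.character(res$rname[keep])
  bad <- setdiff(unique(rname), names(genome$lengths))
  if (length(bad)) {
    stop("alignment contig(s) absent from genome: ",
         paste(bad, collapse = ", "))
  }
  rev <- as.character(res$strand[keep]) == "-"
  # 0-based 5' end: forward = leftmost aligned base, reverse = rightmost
  pos0 <- res$pos[keep] - 1L + ifelse(rev, alen[keep] - 1L, 0L)

  tally <- function(sel) {
    lapply(stats::setNames(nm = names(genome$lengths)), function(ctg) {
      len <- genome$lengths[[ctg]]
      i <- sel & rname == ctg
      if (!any(i)) integer(len) else tabulate(pos0[i] + 1L, nbins = len)
    })
  }
  counts <- tally(rep(TRUE, sum(keep)))
  if (sum(keep) == 0L) {
    warning("no records retained from ", if (is.character(file)) file else
            "alignment file", "; track is all zeros")
  }
  track <- end_count_track(counts, replicate_id, condition)
  if (per_strand) {
    attr(track, "per_strand") <- list(forward = tally(!rev), reverse = tally(rev))
  }
  track
}
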
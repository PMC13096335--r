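#' 5'-base coverage of a tRNA locus
#'
#' Container for per-position counts of read 5' bases within a locus, in
#' 0-based locus coordinates.
#'
#' @param counts non-negative integer vector, one value per locus position.
#' @param locus locus name.
#' @param condition condition label (free text, e.g. `"with_defense"`).
#' @param replicate_id optional replicate label.
#' @param library_size total counts used for depth normalization; defaults
#'   to `sum(counts)` but is normally the library-wide total.
#' @return An object of class `trf_coverage`.
#' @export
trf_coverage <- function(counts, locus, condition, replicate_id = NULL,
                         library_size = sum(counts)) {
  counts <- as.integer(counts)
  if (any(counts < 0L)) stop("counts must be non-negative")
  if (library_size < sum(counts)) {
    stop("library_size smaller than locus counts")
  }
  structure(list(locus = as.character(locus),
                 condition = as.character(condition),
                 replicate_id = replicate_id, counts = counts,
                 library_size = as.numeric(library_size)),
            class = "trf_coverage")
}

#' @export
print.trf_coverage <- function(x, ...) {
  cat("trf_coverage '", x$locus, "' (", x$condition, "): ",
      length(x$counts), " nt, ", sum(x$counts), " locus 5' ends, library ",
      format(x$library_size, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' 5'-base coverage of uniquely aligned reads over a locus
#'
#' Counts the 5' base (forward: leftmost aligned base; reverse: rightmost)
#' of each retained uniquely aligned read that falls inside the locus.
#' Uniqueness is either `"primary_unique"` (default: primary records whose
#' read name has no secondary record anywhere in the file) or `"mapq"`
#' (primary records with MAPQ above 0).
#'
#' @param file indexed BAM path or [Rsamtools::BamFile].
#' @param contig,start,end locus interval, 0-based half-open.
#' @param locus locus name for the result.
#' @param condition condition label.
#' @param replicate_id optional replicate label.
#' @param uniqueness uniqueness rule, see above.
#' @return A [trf_coverage()] of length `end - start`; `library_size` is
#'   the number of retained unique reads file-wide.
#' @export
trf_five_prime_coverage <- function(file, contig, start, end, locus = contig,
                                    condition = "unknown",
                                    replicate_id = NULL,
                                    uniqueness = c("primary_unique", "mapq")) {
  uniqueness <- match.arg(uniqueness)
  if (is.character(file)) {
    if (!file.exists(file)) stop("no such alignment file: ", file)
    idx <- paste0(file, ".bai")
    if (!file.exists(idx) && !file.exists(sub("\\.bam$", ".bai", file))) {
      stop("missing BAM index (.bai) for ", file)
    }
  }
  res <- Rsamtools::scanBam(
    file, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "strand", "pos", "cigar",
               "mapq")))[[1]]
  flag <- res$flag
  mapped <- bitwAnd(flag, 4L) == 0L & !is.na(res$pos)
  primary <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  keep <- mapped & primary
  if (uniqueness == "primary_unique") {
    multi <- unique(res$qname[bitwAnd(flag, 256L) != 0L])
    keep <- keep & !(res$qname %in% multi)
  } else {
    keep <- keep & !is.na(res$mapq) & res$mapq > 0L
  }
  alen <- rep(NA_integer_, length(flag))
  ok <- keep & !is.na(res$cigar)
  if (any(ok)) {
    alen[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[ok])
  }
  keep <- ok
  pos0 <- res$pos[keep] - 1L +
    ifelse(as.character(res$strand[keep]) == "-", alen[keep] - 1L, 0L)
  in_locus <- as.character(res$rname[keep]) == contig &
    pos0 >= start & pos0 < end
  counts <- tabulate(pos0[in_locus] - start + 1L, nbins = end - start)
  trf_coverage(counts, locus = locus, condition = condition,
               replicate_id = replicate_id, library_size = sum(keep))
}

#' Condition coverage ratio and cleavage call for a tRNA locus
#'
#' Computes the per-position ratio of 5'-base coverage between two
#' conditions and calls the cleavage position as the argmax of the ratio
#' (all tied positions reported). By default each condition is depth
#' normalized: the pseudocount is added on the raw-count scale and the
#' result scaled by the condition's library size
#' (`(count + pc) / library_size * 1e6`), so libraries of different depth
#' are comparable; `scale = "raw"` uses `(count + pc)` directly.
#'
#' @param with_defense,without_defense [trf_coverage()] objects over the
#'   same locus (same name and length).
#' @param pc pseudocount in counts, must be positive (default 1).
#' @param scale `"cpm"` (default) or `"raw"`.
#' @param min_ratio calls are only reported where the ratio reaches this
#'   value (default 2); below it `positions` is empty.
#' @return An object of class `cleavage_call`: `locus`, `positions`
#'   (0-based argmax positions of the ratio, possibly empty), `ratio`
#'   (value at the argmax), `ratio_track` (per-position ratios),
#'   `pseudocount`, `scale`.
#' @export
trf_ratio <- function(with_defense, without_defense, pc = 1, scale = c("cpm", "raw"),
                      min_ratio = 2) {
  stopifnot(inherits(with_defense, "trf_coverage"),
            inherits(without_defense, "trf_coverage"))
  scale <- match.arg(scale)
  if (!identical(with_defense$locus, without_defense$locus) ||
      length(with_defense$counts) != length(without_defense$counts)) {
    stop("coverage objects are over different loci")
  }
  if (!is.numeric(pc) || pc <= 0) stop("pseudocount must be > 0")
  val <- function(x) {
    v <- x$counts + pc
    if (scale == "cpm") {
      ls <- if (x$library_size > 0) x$library_size else 1
      v <- v / ls * 1e6
    }
    v
  }
  ratio <- val(with_defense) / val(without_defense)
  peak <- max(ratio)
  positions <- if (peak >= min_ratio) which(ratio == peak) - 1L else integer(0)
  structure(list(locus = with_defense$locus, positions = positions,
                 ratio = if (length(positions)) peak else NA_real_,
                 ratio_track = ratio, pseudocount = pc, scale = scale,
                 min_ratio = min_ratio),
            class = "cleavage_call")
}

#' @export
print.cleavage_call <- function(x, ...) {
  cat("cleavage_call '", x$locus, "': ", sep = "")
  if (length(x$positions)) {
    cat("position(s) ", paste(x$positions, collapse = ", "),
        " (ratio ", format(x$ratio, digits = 3), ")\n", sep = "")
  } else {
    cat("no differential position (max ratio ",
        format(max(x$ratio_track), digits = 3), " < ", x$min_ratio, ")\n",
        sep = "")
  }
  invisible(x)
}
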
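#' Write a per-contig numeric track as bedGraph
#'
#' Consecutive equal values are run-length collapsed; zero runs are omitted
#' so only informative positions are written (0-based half-open intervals).
#'
#' @param values named list of numeric vectors, one per contig (e.g. the
#'   `aggregate` or `smoothed` element of a condition profile, the `fc`
#'   element of a fold-change track, or the `counts` of an end-count track).
#' @param file output path.
#' @param keep_zero also write zero-valued runs (default `FALSE`).
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(values, file, keep_zero = FALSE) {
  gr_list <- lapply(names(values), function(ctg) {
    r <- S4Vectors::Rle(as.numeric(values[[ctg]]))
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r) + 1L
    v <- S4Vectors::runValue(r)
    if (!keep_zero) {
      nz <- v != 0
      starts <- starts[nz]; ends <- ends[nz]; v <- v[nz]
    }
    if (!length(v)) return(NULL)
    GenomicRanges::GRanges(ctg, IRanges::IRanges(starts, ends), score = v)
  })
  gr <- do.call(c, c(gr_list[!vapply(gr_list, is.null, logical(1))],
                     list(GenomicRanges::GRanges())))
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' Write called peaks to BED
#'
#' 0-based half-open BED5: contig, start, end, name, score (the peak's
#' scaled log2FC, capped at 1000).
#'
#' @param peaks peaks data.frame from [call_peaks()]/[emit_peaks()], or a
#'   `peak_set`.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_peaks_bed <- function(peaks, file) {
  if (inherits(peaks, "peak_set")) peaks <- peaks$peaks
  if (nrow(peaks) == 0L) {
    writeLines(character(0), file)
    return(invisible(file))
  }
  gr <- GenomicRanges::GRanges(
    peaks$contig, IRanges::IRanges(peaks$start + 1L, peaks$end),
    name = peaks$name, score = pmax(pmin(peaks$score, 1000), 0))
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' Write a replicate manifest
#'
#' @param tracks list of [end_count_track()]s.
#' @param file output TSV path.
#' @return The path, invisibly.
#' @export
write_track_manifest <- function(tracks, file) {
  m <- data.frame(
    replicate_id = vapply(tracks, `[[`, character(1), "replicate_id"),
    condition = vapply(tracks, `[[`, character(1), "condition"),
    library_size = vapply(tracks, `[[`, numeric(1), "library_size"))
  utils::write.table(m, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
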
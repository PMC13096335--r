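#' Peak-calling thresholds
#'
#' The stringency criteria applied to candidate summits. Defaults reproduce
#' the SITE-seq cleavage-site procedure: smoothed treated signal of at least
#' 1.0 CPM, log2 fold change of at least 2, treated-to-mock ratio of at
#' least 1.2 at the summit, raw 5'-end count of at least 5 within +/-1 bp in
#' at least 2 treated replicates, summits merged within 3 bp, and 3-bp
#' output peaks.
#'
#' @param min_signal minimum smoothed treated signal at the summit (CPM).
#' @param min_log2fc minimum log2 fold change at the summit.
#' @param min_ratio minimum pseudocount-stabilized treated/mock ratio.
#' @param min_raw_count minimum raw 5'-end count a replicate must reach
#'   within the support window to count as supporting.
#' @param support_radius half-width (bp) of the raw-count support window.
#' @param min_supporting_replicates replicates required to support a summit.
#' @param merge_distance summits at most this many bp apart are merged.
#' @param peak_width odd width (bp) of emitted peaks.
#' @return An object of class `peak_thresholds`.
#' @export
peak_thresholds <- function(min_signal = 1.0, min_log2fc = 2.0,
                            min_ratio = 1.2, min_raw_count = 5L,
                            support_radius = 1L,
                            min_supporting_replicates = 2L,
                            merge_distance = 3L, peak_width = 3L) {
  peak_width <- as.integer(peak_width)
  vals <- c(min_signal, min_log2fc, min_ratio, min_raw_count,
            support_radius, min_supporting_replicates, merge_distance,
            peak_width)
  if (any(vals < 0)) stop("thresholds must be non-negative")
  if (peak_width %% 2L == 0L) stop("peak_width must be odd")
  structure(list(min_signal = min_signal, min_log2fc = min_log2fc,
                 min_ratio = min_ratio,
                 min_raw_count = as.integer(min_raw_count),
                 support_radius = as.integer(support_radius),
                 min_supporting_replicates =
                   as.integer(min_supporting_replicates),
                 merge_distance = as.integer(merge_distance),
                 peak_width = peak_width),
            class = "peak_thresholds")
}

# Plateau-tolerant (weak) local maxima: position i qualifies when its value
# is >= both neighbors; a missing neighbor at the array boundary is treated
# as satisfied. Every position of a flat run flanked by lower (or no)
# values qualifies, so a summit smoothed into an exact plateau is not
# prematurely collapsed to one arbitrary end -- the raw-count support
# filter and the merge step (max smoothed signal, ties leftmost) resolve
# the tie downstream. Returns 0-based positions.
local_maxima <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(0L)
  ge_left <- c(TRUE, x[-1L] >= x[-n])
  ge_right <- c(x[-n] >= x[-1L], TRUE)
  which(ge_left & ge_right) - 1L
}

#' Find candidate cleavage summits
#'
#' Scans the smoothed treated profile for plateau-tolerant local maxima
#' (positions whose value is at least that of both neighbors; every
#' position of a flat-topped summit qualifies, so ties are resolved
#' downstream by replicate support and [merge_summits()]) and keeps
#' positions passing all three summit criteria: smoothed treated signal
#' `>= min_signal`, log2 fold change `>= min_log2fc`, and
#' pseudocount-stabilized treated/mock ratio `>= min_ratio`.
#'
#' @param treated,mock smoothed [aggregate_condition()] profiles over
#'   identical contigs.
#' @param fc the [log2fc_profile()] of the two (its pseudocount is reused
#'   for the ratio criterion).
#' @param th a [peak_thresholds()].
#' @return data.frame with columns `contig`, `position` (0-based),
#'   `treated_smoothed`, `mock_smoothed`, `log2fc`, `ratio`, `support`
#'   (`NA` until [replicate_support()] fills it), sorted by
#'   (contig, position).
#' @export
find_summits <- function(treated, mock, fc, th = peak_thresholds()) {
  stopifnot(inherits(fc, "fold_change_track"),
            inherits(th, "peak_thresholds"))
  .check_same_contigs(list(treated$smoothed, mock$smoothed, fc$fc))
  pc <- fc$pseudocount
  out <- lapply(names(treated$smoothed), function(ctg) {
    ts <- treated$smoothed[[ctg]]
    ms <- mock$smoothed[[ctg]]
    pos <- local_maxima(ts)
    if (!length(pos)) return(NULL)
    i <- pos + 1L
    ratio <- (ts[i] + pc) / (ms[i] + pc)
    ok <- ts[i] >= th$min_signal & fc$fc[[ctg]][i] >= th$min_log2fc &
      ratio >= th$min_ratio
    if (!any(ok)) return(NULL)
    data.frame(contig = ctg, position = pos[ok],
               treated_smoothed = ts[i][ok], mock_smoothed = ms[i][ok],
               log2fc = fc$fc[[ctg]][i][ok], ratio = ratio[ok],
               support = NA_integer_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(contig = character(0), position = integer(0),
                      treated_smoothed = numeric(0),
                      mock_smoothed = numeric(0), log2fc = numeric(0),
                      ratio = numeric(0), support = integer(0),
                      stringsAsFactors = FALSE)
  }
  out[order(out$contig, out$position), , drop = FALSE]
}

#' Count treated replicates supporting candidate summits
#'
#' A replicate supports a candidate when its maximum raw 5'-end count over
#' the window `[summit - support_radius, summit + support_radius]` (clipped
#' to the contig) reaches `min_raw_count`.
#'
#' @param candidates data.frame from [find_summits()].
#' @param raw_treated list of treated [end_count_track()]s.
#' @param th a [peak_thresholds()].
#' @return `candidates` with the `support` column filled.
#' @export
replicate_support <- function(candidates, raw_treated,
                              th = peak_thresholds()) {
  if (inherits(raw_treated, "end_count_track")) raw_treated <- list(raw_treated)
  if (length(raw_treated) < 1L) stop("need at least one raw treated track")
  r <- th$support_radius
  candidates$support <- vapply(seq_len(nrow(candidates)), function(i) {
    ctg <- candidates$contig[i]
    p <- candidates$position[i]
    sum(vapply(raw_treated, function(t) {
      x <- t$counts[[ctg]]
      lo <- max(p - r, 0L) + 1L
      hi <- min(p + r, length(x) - 1L) + 1L
      max(x[lo:hi]) >= th$min_raw_count
    }, logical(1)))
  }, integer(1))
  candidates
}

#' Merge nearby summits
#'
#' Same-contig candidates whose consecutive positions differ by at most
#' `merge_distance` are clustered transitively; each cluster is collapsed to
#' its member with the highest smoothed treated signal (ties to the
#' leftmost position).
#'
#' @param candidates data.frame of candidates sorted by (contig, position).
#' @param th a [peak_thresholds()].
#' @return data.frame of merged summits, same columns.
#' @export
merge_summits <- function(candidates, th = peak_thresholds()) {
  if (nrow(candidates) < 2L) return(candidates)
  candidates <- candidates[order(candidates$contig, candidates$position), ,
                           drop = FALSE]
  gap_new <- c(TRUE, candidates$contig[-1L] != candidates$contig[-nrow(candidates)] |
                 diff(candidates$position) > th$merge_distance)
  cluster <- cumsum(gap_new)
  keep <- unlist(lapply(split(seq_len(nrow(candidates)), cluster),
                        function(idx) {
    s <- candidates$treated_smoothed[idx]
    idx[which(s == max(s))[1L]]  # leftmost among ties (rows are sorted)
  }), use.names = FALSE)
  candidates[sort(keep), , drop = FALSE]
}

#' Emit fixed-width peaks around final summits
#'
#' Each summit becomes a half-open 0-based interval of `peak_width` bases
#' centered on it, clipped at contig boundaries (with a warning).
#'
#' @param summits data.frame of final summits (post-merge, post-support).
#' @param genome a [genome_index()].
#' @param th a [peak_thresholds()].
#' @return data.frame of peaks with columns `contig`, `start`, `end`,
#'   `summit`, `midpoint`, `name`, `score` (round(100 x log2FC), capped at
#'   1000) plus the summit score columns.
#' @export
emit_peaks <- function(summits, genome, th = peak_thresholds()) {
  h <- (th$peak_width - 1L) %/% 2L
  len <- genome$lengths[summits$contig]
  start <- pmax(summits$position - h, 0L)
  end <- pmin(summits$position + h + 1L, as.integer(len))
  if (nrow(summits) && any(end - start < th$peak_width)) {
    warning(sum(end - start < th$peak_width),
            " peak(s) clipped at contig boundaries")
  }
  data.frame(contig = summits$contig, start = start, end = end,
             summit = summits$position, midpoint = (start + end) / 2,
             name = if (nrow(summits)) paste0("peak_", seq_len(nrow(summits)))
                    else character(0),
             score = pmin(round(100 * summits$log2fc), 1000),
             treated_smoothed = summits$treated_smoothed,
             mock_smoothed = summits$mock_smoothed,
             log2fc = summits$log2fc, ratio = summits$ratio,
             support = summits$support, stringsAsFactors = FALSE)
}

#' Call cleavage-site peaks from treated and mock replicates
#'
#' End-to-end orchestration: 5'-end extraction (or pre-computed tracks),
#' CPM normalization, per-condition aggregation, smoothing, log2 fold
#' change, summit detection, raw-count replicate support, summit merging
#' and peak emission. Deterministic given inputs and configuration.
#'
#' @param treated,mock lists of BAM paths or [end_count_track()]s (at least
#'   one each).
#' @param genome a [genome_index()].
#' @param cfg a [filter_config()] (used only when BAM paths are given).
#' @param th a [peak_thresholds()].
#' @param pseudocount pseudocount in CPM for the log2FC and ratio criteria.
#' @param smooth_window odd moving-average width in bases.
#' @param edges smoothing edge rule, see [smooth_track()].
#' @return An object of class `peak_set`: the `peaks` data.frame plus the
#'   condition profiles, fold-change track, thresholds and configuration.
#' @seealso [write_peaks_bed()], [peak_table()], [audit_peaks()]
#' @export
call_peaks <- function(treated, mock, genome, cfg = filter_config(),
                       th = peak_thresholds(), pseudocount = 0.1,
                       smooth_window = 5L, edges = "zero") {
  as_tracks <- function(x, condition) {
    if (inherits(x, "end_count_track")) x <- list(x)
    if (length(x) < 1L) stop("need at least one ", condition, " input")
    lapply(seq_along(x), function(i) {
      if (inherits(x[[i]], "end_count_track")) x[[i]]
      else extract_r1_ends(x[[i]], genome,
                           replicate_id = paste0(condition, "_", i),
                           condition = condition, cfg = cfg)
    })
  }
  treated_tracks <- as_tracks(treated, "treated")
  mock_tracks <- as_tracks(mock, "mock")

  tprof <- smooth_profile(
    aggregate_condition(lapply(treated_tracks, cpm_normalize), "treated"),
    w = smooth_window, edges = edges)
  mprof <- smooth_profile(
    aggregate_condition(lapply(mock_tracks, cpm_normalize), "mock"),
    w = smooth_window, edges = edges)
  fc <- log2fc_profile(tprof, mprof, pc = pseudocount)

  cand <- find_summits(tprof, mprof, fc, th)
  cand <- replicate_support(cand, treated_tracks, th)
  cand <- cand[cand$support >= th$min_supporting_replicates, , drop = FALSE]
  cand <- merge_summits(cand, th)
  peaks <- emit_peaks(cand, genome, th)

  structure(list(peaks = peaks, treated_profile = tprof,
                 mock_profile = mprof, fold_change = fc, thresholds = th,
                 pseudocount = pseudocount, smooth_window = smooth_window,
                 genome_lengths = genome$lengths,
                 treated_tracks = treated_tracks, mock_tracks = mock_tracks),
            class = "peak_set")
}

#' Audit a peak set against its thresholds
#'
#' Rechecks, post hoc and independently of the calling path, that every
#' emitted peak satisfies all summit and support criteria.
#'
#' @param ps a `peak_set` from [call_peaks()].
#' @return Invisibly, a logical vector (one per peak, `TRUE` = compliant);
#'   errors if any peak violates a threshold.
#' @export
audit_peaks <- function(ps) {
  stopifnot(inherits(ps, "peak_set"))
  th <- ps$thresholds
  pc <- ps$pseudocount
  ok <- vapply(seq_len(nrow(ps$peaks)), function(i) {
    p <- ps$peaks[i, ]
    ts <- ps$treated_profile$smoothed[[p$contig]][p$summit + 1L]
    ms <- ps$mock_profile$smoothed[[p$contig]][p$summit + 1L]
    fc <- ps$fold_change$fc[[p$contig]][p$summit + 1L]
    support <- sum(vapply(ps$treated_tracks, function(t) {
      x <- t$counts[[p$contig]]
      lo <- max(p$summit - th$support_radius, 0L) + 1L
      hi <- min(p$summit + th$support_radius, length(x) - 1L) + 1L
      max(x[lo:hi]) >= th$min_raw_count
    }, logical(1)))
    ts >= th$min_signal && fc >= th$min_log2fc &&
      (ts + pc) / (ms + pc) >= th$min_ratio &&
      support >= th$min_supporting_replicates
  }, logical(1))
  if (!all(ok)) stop(sum(!ok), " peak(s) violate the calling thresholds")
  invisible(ok)
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set:", nrow(x$peaks), "peak(s) over",
      length(x$genome_lengths), "contig(s)\n")
  cat("  replicates:", length(x$treated_tracks), "treated,",
      length(x$mock_tracks), "mock\n")
  cat("  thresholds: signal >=", x$thresholds$min_signal,
      "CPM, log2FC >=", x$thresholds$min_log2fc,
      ", ratio >=", x$thresholds$min_ratio,
      ", support >=", x$thresholds$min_supporting_replicates, "\n")
  if (nrow(x$peaks)) {
    print(utils::head(x$peaks[c("contig", "start", "end", "summit",
                                "log2fc", "support")], 10))
    if (nrow(x$peaks) > 10) cat("  ...", nrow(x$peaks) - 10, "more\n")
  }
  invisible(x)
}

#' @export
summary.peak_set <- function(object, ...) {
  p <- object$peaks
  cat("Cleavage-site peak calling\n")
  cat("  peaks:", nrow(p), "\n")
  if (nrow(p)) {
    cat("  log2FC: median", format(stats::median(p$log2fc), digits = 3),
        "range", paste(format(range(p$log2fc), digits = 3), collapse = " .. "),
        "\n")
    cat("  replicate support:",
        paste(names(table(p$support)), table(p$support),
              sep = "x", collapse = ", "), "\n")
  }
  invisible(object)
}

#' Plot a called peak set
#'
#' Draws the smoothed treated and mock CPM profiles for one contig with the
#' called summits marked.
#'
#' @param x a `peak_set`.
#' @param contig contig to draw (default: the first).
#' @param ... passed to [graphics::plot()].
#' @export
plot.peak_set <- function(x, contig = names(x$genome_lengths)[1], ...) {
  ts <- x$treated_profile$smoothed[[contig]]
  ms <- x$mock_profile$smoothed[[contig]]
  pos <- seq_along(ts) - 1L
  graphics::plot(pos, ts, type = "l", col = "firebrick",
                 xlab = paste0(contig, " position (bp)"),
                 ylab = "smoothed CPM", ...)
  graphics::lines(pos, ms, col = "grey40")
  pk <- x$peaks[x$peaks$contig == contig, ]
  if (nrow(pk)) graphics::abline(v = pk$summit, col = "steelblue", lty = 3)
  graphics::legend("topright", legend = c("treated", "mock", "summit"),
                   col = c("firebrick", "grey40", "steelblue"),
                   lty = c(1, 1, 3), bty = "n")
  invisible(x)
}

#' Export the per-peak score table
#'
#' @param ps a `peak_set`.
#' @param file optional TSV path to write.
#' @param min_log2fc_export optional strict lower bound on log2FC applied to
#'   the exported table only (visualization-style filter, `log2fc > cutoff`).
#' @param midpoint_kb add peak midpoints in kilobases.
#' @return The (possibly filtered) peaks data.frame, invisibly when written.
#' @export
peak_table <- function(ps, file = NULL, min_log2fc_export = NULL,
                       midpoint_kb = TRUE) {
  stopifnot(inherits(ps, "peak_set"))
  p <- ps$peaks
  if (!is.null(min_log2fc_export)) p <- p[p$log2fc > min_log2fc_export, ,
                                          drop = FALSE]
  if (midpoint_kb) p$midpoint_kb <- p$midpoint / 1000
  if (!is.null(file)) {
    utils::write.table(p, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(p))
  }
  p
}
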
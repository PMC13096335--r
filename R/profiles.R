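#' Convert a 5'-end count track to counts per million
#'
#' Each position's count is scaled by the replicate's total retained events:
#' `cpm = count / library_size * 1e6`. Scaling uses the whole-library size
#' across all contigs, so CPM values sum to one million per replicate.
#'
#' @param track an [end_count_track()] with `library_size > 0`.
#' @return An object of class `cpm_track`: `replicate_id` plus a per-contig
#'   list of numeric CPM vectors.
#' @export
cpm_normalize <- function(track) {
  stopifnot(inherits(track, "end_count_track"))
  if (track$library_size <= 0) stop("empty replicate: library_size is 0")
  cpm <- lapply(track$counts, function(x) as.numeric(x) / track$library_size * 1e6)
  structure(list(replicate_id = track$replicate_id,
                 condition = track$condition, cpm = cpm),
            class = "cpm_track")
}

.check_same_contigs <- function(lists) {
  ref <- lists[[1]]
  ref_len <- vapply(ref, length, integer(1))
  for (x in lists[-1]) {
    if (!identical(names(x), names(ref)) ||
        !identical(vapply(x, length, integer(1)), ref_len)) {
      stop("tracks have mismatched contig sets or lengths")
    }
  }
  invisible(TRUE)
}

#' Sum replicate CPM tracks into a condition profile
#'
#' @param tracks list of `cpm_track` objects over identical contigs.
#' @param condition condition label; defaults to the tracks' shared label.
#' @return An object of class `condition_profile` with the element-wise
#'   `aggregate`; `smoothed` is filled by [smooth_profile()].
#' @export
aggregate_condition <- function(tracks, condition = NULL) {
  if (inherits(tracks, "cpm_track")) tracks <- list(tracks)
  if (length(tracks) < 1L) stop("need at least one track")
  stopifnot(all(vapply(tracks, inherits, logical(1), "cpm_track")))
  .check_same_contigs(lapply(tracks, `[[`, "cpm"))
  if (is.null(condition)) condition <- tracks[[1]]$condition
  agg <- lapply(stats::setNames(nm = names(tracks[[1]]$cpm)), function(ctg) {
    Reduce(`+`, lapply(tracks, function(t) t$cpm[[ctg]]))
  })
  structure(list(condition = condition, aggregate = agg, smoothed = NULL,
                 window_w = NA_integer_,
                 n_replicates = length(tracks)),
            class = "condition_profile")
}

#' Moving-average smoothing with zero-padded edges
#'
#' `out[i]` is the mean of the `w` input values centred on `i`, with
#' out-of-range positions contributing zero (the divisor is always `w`).
#'
#' @param x numeric vector.
#' @param w odd window width, `1 <= w <= length(x)`; default 5.
#' @param edges `"zero"` (zero-padding, the default) or `"shrink"`
#'   (divisor shrinks to the in-range window size at the edges).
#' @return Numeric vector of `length(x)`.
#' @export
#' @examples
#' smooth_track(c(0, 0, 5, 0, 0), w = 5)
smooth_track <- function(x, w = 5L, edges = c("zero", "shrink")) {
  edges <- match.arg(edges)
  w <- as.integer(w)
  if (w %% 2L == 0L) stop("smoothing window must be odd")
  if (w < 1L || w > length(x)) stop("window must be in [1, length(x)]")
  if (w == 1L) return(as.numeric(x))
  h <- (w - 1L) %/% 2L
  padded <- c(numeric(h), as.numeric(x), numeric(h))
  sums <- as.numeric(stats::filter(padded, rep(1, w), sides = 2))
  sums <- sums[(h + 1L):(h + length(x))]
  if (edges == "zero") {
    sums / w
  } else {
    n <- length(x)
    denom <- pmin(seq_len(n) + h, n) - pmax(seq_len(n) - h, 1L) + 1L
    sums / denom
  }
}

#' Smooth a condition profile
#'
#' @param profile a `condition_profile` from [aggregate_condition()].
#' @param w odd moving-average width in bases (default 5).
#' @param edges edge rule, see [smooth_track()].
#' @return The profile with `smoothed` filled and `window_w = w`.
#' @export
smooth_profile <- function(profile, w = 5L, edges = "zero") {
  stopifnot(inherits(profile, "condition_profile"))
  profile$smoothed <- lapply(profile$aggregate, smooth_track, w = w,
                             edges = edges)
  profile$window_w <- as.integer(w)
  profile
}

#' @export
print.condition_profile <- function(x, ...) {
  cat("condition_profile '", x$condition, "': ", length(x$aggregate),
      " contig(s), ", x$n_replicates, " replicate(s), ",
      if (is.null(x$smoothed)) "unsmoothed"
      else paste0("smoothed (w = ", x$window_w, ")"), "\n", sep = "")
  invisible(x)
}

#' Log2 fold-change track between two smoothed condition profiles
#'
#' `out[i] = log2((treated.smoothed[i] + pc) / (mock.smoothed[i] + pc))`.
#' The pseudocount `pc` (in CPM) keeps the ratio finite at uncovered
#' positions and is recorded on the result for downstream use.
#'
#' @param treated,mock smoothed `condition_profile`s over identical contigs.
#' @param pc pseudocount in CPM, must be positive (default 0.1).
#' @return An object of class `fold_change_track` with per-contig `fc`
#'   vectors and the `pseudocount` used.
#' @export
log2fc_profile <- function(treated, mock, pc = 0.1) {
  stopifnot(inherits(treated, "condition_profile"),
            inherits(mock, "condition_profile"))
  if (is.null(treated$smoothed) || is.null(mock$smoothed)) {
    stop("profiles must be smoothed first (see smooth_profile)")
  }
  if (!is.numeric(pc) || pc <= 0) stop("pseudocount must be > 0")
  .check_same_contigs(list(treated$smoothed, mock$smoothed))
  fc <- lapply(stats::setNames(nm = names(treated$smoothed)), function(ctg) {
    log2((treated$smoothed[[ctg]] + pc) / (mock$smoothed[[ctg]] + pc))
  })
  structure(list(fc = fc, pseudocount = pc), class = "fold_change_track")
}
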
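#' Per-genome annotation for neighborhood analysis
#'
#' Holds one genome's length, the focal gene interval and its tRNA gene
#' intervals. All intervals are 0-based half-open.
#'
#' @param genome_id genome identifier.
#' @param genome_length genome length in bases.
#' @param focal_gene integer vector `c(start, end)`, nonempty, within the
#'   genome.
#' @param trna_genes two-column matrix or data.frame of tRNA `start`,`end`
#'   intervals (possibly zero rows).
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_id, genome_length, focal_gene,
                              trna_genes = cbind(integer(0), integer(0))) {
  genome_length <- as.numeric(genome_length)
  focal_gene <- as.numeric(focal_gene)
  trna_genes <- as.matrix(trna_genes)
  if (ncol(trna_genes) < 2L && nrow(trna_genes) > 0L) {
    stop("trna_genes needs start and end columns")
  }
  if (length(focal_gene) != 2L || focal_gene[1] >= focal_gene[2]) {
    stop("focal_gene must be a nonempty [start, end) interval")
  }
  ivs <- rbind(focal_gene, trna_genes[, 1:2, drop = FALSE])
  if (any(ivs[, 1] < 0) || any(ivs[, 2] > genome_length)) {
    stop("intervals outside [0, genome_length)")
  }
  structure(list(genome_id = as.character(genome_id),
                 genome_length = genome_length,
                 focal_gene = focal_gene,
                 trna_genes = matrix(as.numeric(trna_genes[, 1:2]),
                                     ncol = 2,
                                     dimnames = list(NULL, c("start", "end")))),
            class = "genome_annotation")
}

#' Read genome annotations from TSV
#'
#' Expects columns `genome_id`, `genome_length`, `focal_start`, `focal_end`,
#' `trna_start`, `trna_end`, one row per tRNA gene; genomes without tRNAs
#' carry a single row with empty/NA tRNA columns.
#'
#' @param file TSV path.
#' @return List of [genome_annotation()] objects.
#' @export
read_annotation_tsv <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("genome_id", "genome_length", "focal_start", "focal_end",
            "trna_start", "trna_end")
  if (!all(need %in% names(d))) {
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  }
  lapply(split(d, factor(d$genome_id, levels = unique(d$genome_id))),
         function(g) {
    tr <- g[!is.na(g$trna_start) & !is.na(g$trna_end),
            c("trna_start", "trna_end"), drop = FALSE]
    genome_annotation(g$genome_id[1], g$genome_length[1],
                      c(g$focal_start[1], g$focal_end[1]), as.matrix(tr))
  })
}

#' Proximal vs genome-wide tRNA gene density
#'
#' The proximal region is the focal gene body extended by `flank` bases on
#' each side, clipped to the genome. Proximal density is the number of tRNA
#' genes overlapping that region by at least one base divided by the
#' (clipped) region length; genome-wide density is the total tRNA count
#' divided by the genome length.
#'
#' @param ann a [genome_annotation()].
#' @param flank flank size in bp (default 1000).
#' @param overlap `"any"` (default, >= 1 bp overlap counts) or `"within"`
#'   (tRNA must lie entirely inside the region).
#' @param include_gene_body include the focal gene body in the region
#'   (default `TRUE`).
#' @return One-row data.frame: `genome_id`, `proximal_density`,
#'   `genomewide_density`, `difference` (proximal minus genome-wide),
#'   densities in tRNA genes per bp.
#' @export
trna_density <- function(ann, flank = 1000L, overlap = c("any", "within"),
                         include_gene_body = TRUE) {
  stopifnot(inherits(ann, "genome_annotation"))
  overlap <- match.arg(overlap)
  tr <- ann$trna_genes
  in_iv <- function(lo, hi) {
    if (nrow(tr) == 0L) return(logical(0))
    if (overlap == "any") tr[, "start"] < hi & tr[, "end"] > lo
    else tr[, "start"] >= lo & tr[, "end"] <= hi
  }
  if (include_gene_body) {
    lo <- max(ann$focal_gene[1] - flank, 0)
    hi <- min(ann$focal_gene[2] + flank, ann$genome_length)
    region_len <- hi - lo
    n_prox <- sum(in_iv(lo, hi))
  } else {
    # flanks-only variant kept for sensitivity analysis
    up_lo <- max(ann$focal_gene[1] - flank, 0); up_hi <- ann$focal_gene[1]
    dn_lo <- ann$focal_gene[2]
    dn_hi <- min(ann$focal_gene[2] + flank, ann$genome_length)
    region_len <- (up_hi - up_lo) + (dn_hi - dn_lo)
    n_prox <- sum(in_iv(up_lo, up_hi) | in_iv(dn_lo, dn_hi))
  }
  if (region_len <= 0) stop("zero-length proximal region")
  prox <- n_prox / region_len
  gw <- nrow(ann$trna_genes) / ann$genome_length
  data.frame(genome_id = ann$genome_id, proximal_density = prox,
             genomewide_density = gw, difference = prox - gw,
             stringsAsFactors = FALSE)
}

#' One-sided paired Wilcoxon signed-rank test on density differences
#'
#' Tests whether proximal tRNA density exceeds genome-wide density across
#' genomes (alternative "greater"). Zero differences are dropped; absolute
#' differences are ranked with midranks for ties; the statistic `W` is the
#' sum of ranks of positive differences. The p-value is computed by exact
#' enumeration of sign assignments when the effective sample size is at
#' most 25 and there are no ties, and otherwise by the normal approximation
#' with tie and continuity corrections.
#'
#' @param pairs data.frame with a `difference` column (e.g. rows of
#'   [trna_density()] results bound together), or a numeric vector of
#'   paired differences.
#' @param exact_max largest tie-free effective n for which the exact
#'   distribution is used (default 25).
#' @return An object of class `wilcoxon_result`: `statistic` (W),
#'   `p_value`, `n_effective`, `alternative`, `method`.
#' @export
paired_wilcoxon_greater <- function(pairs, exact_max = 25L) {
  d <- if (is.data.frame(pairs)) pairs$difference else as.numeric(pairs)
  if (length(d) < 1L) stop("need at least one pair")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate: no nonzero differences")
  ties <- anyDuplicated(abs(d)) > 0L
  use_exact <- n <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(d, alternative = "greater", mu = 0,
                       exact = use_exact, correct = TRUE))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_effective = n, alternative = "greater",
                 method = if (use_exact) "exact enumeration"
                          else "normal approximation (tie + continuity corrected)"),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat("One-sided paired Wilcoxon signed-rank test (greater)\n")
  cat("  W =", x$statistic, ", n =", x$n_effective,
      ", p =", format(x$p_value, digits = 3), "\n")
  cat("  method:", x$method, "\n")
  invisible(x)
}

#' Bootstrap confidence interval for a difference of group medians
#'
#' Each iteration independently resamples both groups with replacement at
#' their own sizes and records `median(A*) - median(B*)`; the interval is
#' the 2.5th and 97.5th percentiles of the resulting distribution
#' (linear-interpolation quantile rule). Deterministic given `seed`.
#'
#' @param group_a,group_b nonempty numeric vectors.
#' @param n_iter bootstrap iterations (default 10000).
#' @param seed integer RNG seed (required for reproducibility).
#' @param conf confidence level (default 0.95).
#' @return An object of class `bootstrap_ci`: `point_estimate`
#'   (`median(A) - median(B)`), `lower`, `upper`, `n_iterations`, `seed`.
#' @export
bootstrap_median_diff <- function(group_a, group_b, n_iter = 10000L,
                                  seed = 1L, conf = 0.95) {
  if (length(group_a) < 1L || length(group_b) < 1L) {
    stop("both groups must be nonempty")
  }
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop("n_iter must be >= 1")
  boot <- with_seed(seed, {
    # resample from the sorted values so the CI depends only on the
    # empirical distributions, not on input order
    sa <- sort(group_a); sb <- sort(group_b)
    na <- length(sa); nb <- length(sb)
    ma <- matrix(sample(sa, na * n_iter, replace = TRUE), nrow = n_iter)
    mb <- matrix(sample(sb, nb * n_iter, replace = TRUE), nrow = n_iter)
    apply(ma, 1L, stats::median) - apply(mb, 1L, stats::median)
  })
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(list(point_estimate = stats::median(group_a) -
                   stats::median(group_b),
                 lower = ci[1], upper = ci[2], n_iterations = n_iter,
                 seed = seed, conf = conf),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat("Bootstrap CI for difference of medians (", x$n_iterations,
      " iterations, seed ", x$seed, ")\n", sep = "")
  cat("  estimate ", format(x$point_estimate, digits = 4), ", ",
      100 * x$conf, "% CI [", format(x$lower, digits = 4), ", ",
      format(x$upper, digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Gene-neighborhood tRNA-density analysis across genomes
#'
#' Computes the paired proximal vs genome-wide tRNA densities for every
#' genome, the one-sided paired Wilcoxon signed-rank test, and the
#' bootstrap CI of the difference of group medians (groups resampled
#' independently).
#'
#' @param annotations list of [genome_annotation()] objects (or a TSV path
#'   accepted by [read_annotation_tsv()]).
#' @param flank flank size in bp (default 1000).
#' @param n_boot bootstrap iterations (default 10000).
#' @param seed RNG seed for the bootstrap.
#' @param ... passed to [trna_density()].
#' @return An object of class `trna_neighborhood`: `table` (one row per
#'   genome), `wilcoxon` (`NULL`, with a message, when the test is
#'   degenerate), `bootstrap`, `flank`.
#' @export
neighborhood_table <- function(annotations, flank = 1000L, n_boot = 10000L,
                               seed = 1L, ...) {
  if (is.character(annotations)) {
    annotations <- read_annotation_tsv(annotations)
  }
  tab <- do.call(rbind, lapply(annotations, trna_density, flank = flank, ...))
  rownames(tab) <- NULL
  wil <- if (sum(tab$difference != 0) < 2L) {
    message("Wilcoxon test not performed: fewer than two nonzero paired ",
            "differences (degenerate)")
    NULL
  } else {
    paired_wilcoxon_greater(tab)
  }
  boot <- bootstrap_median_diff(tab$proximal_density,
                                tab$genomewide_density,
                                n_iter = n_boot, seed = seed)
  structure(list(table = tab, wilcoxon = wil, bootstrap = boot,
                 flank = as.integer(flank)),
            class = "trna_neighborhood")
}

#' @export
print.trna_neighborhood <- function(x, ...) {
  cat("tRNA gene-neighborhood analysis (", nrow(x$table), " genomes, +/-",
      x$flank, " bp)\n", sep = "")
  cat("  median proximal density   ",
      format(stats::median(x$table$proximal_density), digits = 4), "/bp\n")
  cat("  median genome-wide density",
      format(stats::median(x$table$genomewide_density), digits = 4), "/bp\n")
  if (!is.null(x$wilcoxon)) print(x$wilcoxon)
  print(x$bootstrap)
  invisible(x)
}

#' Write the neighborhood analysis to disk
#'
#' @param x a `trna_neighborhood`.
#' @param table_file TSV path for the per-genome density table.
#' @param summary_file optional JSON path for `{W, p, n, CI}`.
#' @return `x`, invisibly.
#' @export
write_neighborhood <- function(x, table_file, summary_file = NULL) {
  stopifnot(inherits(x, "trna_neighborhood"))
  utils::write.table(x$table, table_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(summary_file)) {
    s <- list(W = if (is.null(x$wilcoxon)) NA else x$wilcoxon$statistic,
              p = if (is.null(x$wilcoxon)) NA else x$wilcoxon$p_value,
              n = nrow(x$table),
              ci = c(x$bootstrap$lower, x$bootstrap$upper),
              point_estimate = x$bootstrap$point_estimate,
              quantile_rule = "linear interpolation (type 7)")
    jsonlite::write_json(s, summary_file, auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}
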
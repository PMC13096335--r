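test_that("summit criteria admit a clear enrichment and reject weak fold change", {
  mock0 <- fake_profile(list(chr = numeric(9)), condition = "mock")
  tp <- fake_profile(list(chr = c(0, 0, 0, 0, 2, 0, 0, 0, 0)))
  fc <- log2fc_profile(tp, mock0, pc = 0.1)
  cand <- find_summits(tp, mock0, fc)
  expect_equal(cand$position, 4L)
  expect_equal(cand$log2fc, log2(2.1 / 0.1), tolerance = 1e-12)
  expect_equal(cand$ratio, 21, tolerance = 1e-12)

  # same shape but mock signal tuned so log2FC = 1.5 < 2: excluded
  m <- (2.1 / 2^1.5) - 0.1
  mp <- fake_profile(list(chr = c(0, 0, 0, 0, m, 0, 0, 0, 0)),
                     condition = "mock")
  fc2 <- log2fc_profile(tp, mp, pc = 0.1)
  expect_equal(fc2$fc$chr[5], 1.5)
  expect_equal(nrow(find_summits(tp, mp, fc2)), 0L)

  # flat equal profiles: no enrichment anywhere
  flat <- fake_profile(list(chr = rep(5, 9)))
  flat_m <- fake_profile(list(chr = rep(5, 9)), condition = "mock")
  fc3 <- log2fc_profile(flat, flat_m, pc = 0.1)
  expect_equal(nrow(find_summits(flat, flat_m, fc3)), 0L)
})

test_that("local maxima agree with the brute-force oracle, plateaus included", {
  set.seed(21)
  for (i in 1:100) {
    x <- if (i %% 2 == 0) runif(1000) else round(runif(1000, 0, 5)) / 2
    expect_identical(cutmap:::local_maxima(x), locmax_oracle(x))
  }
})

test_that("replicate support counts raw maxima over the +/-1 bp window", {
  cand <- data.frame(contig = "chr", position = 50L, treated_smoothed = 5,
                     mock_smoothed = 0, log2fc = 5, ratio = 50,
                     support = NA_integer_)
  mk <- function(at, count) {
    v <- integer(100)
    v[at + 1L] <- count
    end_count_track(list(chr = v), "r", "treated")
  }
  # per-replicate window maxima (6, 4, 0): only one supporting replicate
  got <- replicate_support(cand, list(mk(50, 6L), mk(50, 4L), mk(50, 0L)))
  expect_equal(got$support, 1L)
  # (5, 5, 0): the >= 5 rule is inclusive
  got <- replicate_support(cand, list(mk(50, 5L), mk(50, 5L), mk(50, 0L)))
  expect_equal(got$support, 2L)
  # raw count at summit+1 only still lies inside the window
  got <- replicate_support(cand, list(mk(51, 5L), mk(49, 5L), mk(53, 9L)))
  expect_equal(got$support, 2L)
})

test_that("summit merging clusters within 3 bp and keeps the strongest (ties leftmost)", {
  mk <- function(pos, sm) {
    data.frame(contig = "chr", position = as.integer(pos),
               treated_smoothed = sm, mock_smoothed = 0, log2fc = 5,
               ratio = 50, support = 3L)
  }
  m <- merge_summits(rbind(mk(100, 3), mk(102, 5)))
  expect_equal(m$position, 102L)
  m <- merge_summits(rbind(mk(100, 3), mk(104, 5)))
  expect_equal(m$position, c(100L, 104L))
  m <- merge_summits(rbind(mk(100, 4), mk(103, 4)))
  expect_equal(m$position, 100L)
  # transitive chain: 100-103-106 all merge although 100 and 106 are 6 apart
  m <- merge_summits(rbind(mk(100, 1), mk(103, 9), mk(106, 2)))
  expect_equal(m$position, 103L)
  # different contigs never merge
  two <- rbind(mk(100, 3), mk(101, 5))
  two$contig <- c("a", "b")
  expect_equal(nrow(merge_summits(two)), 2L)
})

test_that("emitted peaks are 3-bp intervals centered on the summit, clipped at edges", {
  g <- genome_index(c(chr = 200L))
  mk <- function(pos) {
    data.frame(contig = "chr", position = as.integer(pos),
               treated_smoothed = 5, mock_smoothed = 0, log2fc = 4.3,
               ratio = 50, support = 3L)
  }
  p <- emit_peaks(mk(100), g)
  expect_equal(c(p$start, p$end), c(99L, 102L))
  expect_equal(p$midpoint, 100.5)
  expect_equal(p$score, round(100 * 4.3))

  expect_warning(p0 <- emit_peaks(mk(0), g), "clipped")
  expect_equal(c(p0$start, p0$end), c(0L, 2L))
})

test_that("peak midpoints convert to kilobases in the exported table", {
  s <- standard_siteseq(seed = 31, n_sites = 3L, genome_length = 20000L)
  ps <- call_peaks(as.list(s$sim$treated), as.list(s$sim$mock), s$genome)
  tab <- peak_table(ps)
  expect_equal(tab$midpoint_kb, tab$midpoint / 1000)
  expect_equal(tab$midpoint, (tab$start + tab$end) / 2)
  # strict export filter drops, never adds
  expect_lte(nrow(peak_table(ps, min_log2fc_export = 2)), nrow(tab))
})

test_that("planted sites are recovered exactly and audits pass", {
  s <- standard_siteseq(seed = 41, n_sites = 5L, genome_length = 20000L)
  ps <- call_peaks(as.list(s$sim$treated), as.list(s$sim$mock), s$genome)
  expect_equal(nrow(ps$peaks), 5L)
  expect_true(all(vapply(s$sites$position,
                         function(p) any(abs(ps$peaks$summit - p) <= 1),
                         logical(1))))
  expect_true(all(ps$peaks$end - ps$peaks$start == 3L))
  expect_silent(audit_peaks(ps))
  # merged summits are pairwise farther apart than the merge distance
  expect_true(all(diff(ps$peaks$summit) > ps$thresholds$merge_distance))
})

test_that("raising any threshold never increases the number of peaks", {
  s <- standard_siteseq(seed = 51, n_sites = 5L, genome_length = 20000L)
  tracks_t <- as.list(s$sim$treated)
  tracks_m <- as.list(s$sim$mock)
  base_n <- nrow(call_peaks(tracks_t, tracks_m, s$genome)$peaks)
  bumps <- list(peak_thresholds(min_signal = 10),
                peak_thresholds(min_log2fc = 5),
                peak_thresholds(min_ratio = 10),
                peak_thresholds(min_raw_count = 15L),
                peak_thresholds(min_supporting_replicates = 3L))
  for (th in bumps) {
    expect_lte(nrow(call_peaks(tracks_t, tracks_m, s$genome,
                               th = th)$peaks), base_n)
  }
})

test_that("comparing a replicate against itself yields no peaks", {
  s <- standard_siteseq(seed = 61, n_sites = 0L, genome_length = 10000L)
  f <- s$sim$treated[1]
  ps <- call_peaks(list(f), list(f), s$genome)
  expect_equal(nrow(ps$peaks), 0L)
})
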
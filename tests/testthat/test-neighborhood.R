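test_that("tRNA density pairs proximal and genome-wide rates per genome", {
  ann <- genome_annotation("g1", 10000, c(4000, 4500),
                           rbind(c(3500, 3576), c(9000, 9076)))
  d <- trna_density(ann, flank = 1000)
  expect_equal(d$proximal_density, 1 / 2500)
  expect_equal(d$genomewide_density, 2 / 10000)
  expect_equal(d$difference, 4e-4 - 2e-4)

  none <- genome_annotation("g2", 10000, c(4000, 4500))
  d0 <- trna_density(none)
  expect_equal(c(d0$proximal_density, d0$genomewide_density), c(0, 0))
})

test_that("a 1-bp overlap with the proximal region boundary counts (and 'within' does not)", {
  # proximal region is [3000, 5500); tRNA [2925, 3001) pokes 1 bp in
  ann <- genome_annotation("g", 10000, c(4000, 4500), rbind(c(2925, 3001)))
  expect_equal(trna_density(ann)$proximal_density, 1 / 2500)
  expect_equal(trna_density(ann, overlap = "within")$proximal_density, 0)
  # region clipped at the genome edge shortens the denominator
  edge <- genome_annotation("e", 5000, c(200, 700), rbind(c(100, 176)))
  expect_equal(trna_density(edge)$proximal_density, 1 / (1700 - 0))
})

test_that("signed-rank statistic and exact p match enumeration", {
  r <- paired_wilcoxon_greater(c(1, 2, 3))
  expect_equal(r$statistic, 6)
  expect_equal(r$p_value, 1 / 8)
  expect_equal(r$n_effective, 3L)

  r <- paired_wilcoxon_greater(c(-1, -2, -3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # zero differences are dropped before ranking
  r <- paired_wilcoxon_greater(c(0, 1, 2, 3, 0))
  expect_equal(r$n_effective, 3L)
  expect_equal(r$statistic, 6)

  expect_error(paired_wilcoxon_greater(c(0, 0)), "degenerate")

  set.seed(5)
  for (i in 1:5) {
    d <- round(rnorm(8), 6)  # continuous: tie-free
    got <- paired_wilcoxon_greater(d)
    ora <- wilcoxon_enum_oracle(d)
    expect_equal(got$statistic, ora$W)
    expect_equal(got$p_value, ora$p)
  }
})

test_that("all-positive differences give the analytic maximum W = n(n+1)/2", {
  set.seed(6)
  d <- abs(rnorm(296)) + 1e-6
  r <- paired_wilcoxon_greater(d)
  expect_equal(r$statistic, 296 * 297 / 2)
  expect_equal(r$statistic, 43956)
  expect_lt(r$p_value, 1e-40)
})

test_that("positive and negative rank sums partition n(n+1)/2 for tie-free data", {
  set.seed(7)
  for (i in 1:10) {
    d <- rnorm(20)
    w_pos <- paired_wilcoxon_greater(d)$statistic
    w_neg <- paired_wilcoxon_greater(-d)$statistic
    expect_equal(w_pos + w_neg, 20 * 21 / 2)
  }
})

test_that("exact and large-sample p agree closely at moderate n", {
  set.seed(8)
  for (i in 1:10) {
    d <- rnorm(15, mean = 0.3)
    p_exact <- paired_wilcoxon_greater(d, exact_max = 25L)$p_value
    p_approx <- paired_wilcoxon_greater(d, exact_max = 0L)$p_value
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("bootstrap CI is degenerate for constant groups and order-invariant", {
  b <- bootstrap_median_diff(rep(3, 10), rep(3, 10), n_iter = 200, seed = 1)
  expect_equal(c(b$point_estimate, b$lower, b$upper), c(0, 0, 0))

  b <- bootstrap_median_diff(rep(4, 10), rep(3, 10), n_iter = 200, seed = 1)
  expect_equal(c(b$lower, b$upper), c(1, 1))

  set.seed(9)
  a <- rnorm(40); g2 <- rnorm(40)
  b1 <- bootstrap_median_diff(a, g2, n_iter = 500, seed = 7)
  b2 <- bootstrap_median_diff(sample(a), sample(g2), n_iter = 500, seed = 7)
  expect_equal(c(b1$lower, b1$upper), c(b2$lower, b2$upper))
  expect_error(bootstrap_median_diff(numeric(0), 1:3), "nonempty")
})

test_that("neighborhood_table orchestrates densities, test, and CI", {
  sim <- simulate_neighborhood(80, enrichment = 8, seed = 13)
  nt <- neighborhood_table(sim$annotations, n_boot = 1000, seed = 14)
  expect_equal(nrow(nt$table), 80L)
  expect_lt(nt$wilcoxon$p_value, 0.05)
  expect_lte(nt$bootstrap$lower, nt$bootstrap$upper)
  expect_gt(nt$bootstrap$point_estimate, 0)

  # single genome: density row is produced, test is declined
  one <- sim$annotations[1]
  expect_message(nt1 <- neighborhood_table(one, n_boot = 100, seed = 1),
                 "degenerate")
  expect_equal(nrow(nt1$table), 1L)
  expect_null(nt1$wilcoxon)
})

test_that("annotation TSV round-trips through the reader", {
  tsv <- tempfile(fileext = ".tsv")
  d <- data.frame(genome_id = c("g1", "g1", "g2"),
                  genome_length = c(10000, 10000, 8000),
                  focal_start = c(4000, 4000, 100),
                  focal_end = c(4500, 4500, 800),
                  trna_start = c(3500, 9000, NA),
                  trna_end = c(3576, 9076, NA))
  write.table(d, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  anns <- read_annotation_tsv(tsv)
  expect_length(anns, 2L)
  expect_equal(nrow(anns$g1$trna_genes), 2L)
  expect_equal(nrow(anns$g2$trna_genes), 0L)
  expect_equal(trna_density(anns$g1)$proximal_density, 1 / 2500)
})
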
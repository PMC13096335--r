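test_that("simulators are bit-reproducible given a seed", {
  fa1 <- tempfile(fileext = ".fa"); fa2 <- tempfile(fileext = ".fa")
  g1 <- simulate_genome(2000, seed = 4, fasta = fa1)
  g2 <- simulate_genome(2000, seed = 4, fasta = fa2)
  expect_identical(readLines(fa1), readLines(fa2))
  expect_identical(g1$truth, g2$truth)
  g3 <- simulate_genome(2000, seed = 5)
  expect_false(identical(get_sequence(g1$genome, "sim", 0, 2000),
                         get_sequence(g3$genome, "sim", 0, 2000)))

  s1 <- simulate_trf(seed = 2)
  s2 <- simulate_trf(seed = 2)
  expect_identical(s1$with_defense$counts, s2$with_defense$counts)

  n1 <- simulate_neighborhood(5, seed = 3)
  n2 <- simulate_neighborhood(5, seed = 3)
  expect_identical(n1$annotations, n2$annotations)
})

test_that("simulators restore the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_genome(500, seed = 1))
  invisible(simulate_trf(seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("extract_r1_ends reproduces the simulator's internal 5'-end tally exactly", {
  g <- simulate_genome(8000, seed = 23)$genome
  truth <- sim_truth(data.frame(contig = "sim", position = c(2000L, 5000L),
                                excess = 15),
                     background_rate = 0.05, n_treated = 2L, n_mock = 2L,
                     seed = 24)
  sim <- simulate_site_seq(g, truth, out_dir = tempfile("rt"))
  files <- c(sim$treated, sim$mock)
  for (i in seq_along(files)) {
    got <- extract_r1_ends(files[i], g, sim$tracks[[i]]$replicate_id,
                           sim$tracks[[i]]$condition)
    expect_identical(got$counts, sim$tracks[[i]]$counts)
    expect_equal(got$library_size, sim$tracks[[i]]$library_size)
  }
  expect_true(file.exists(file.path(dirname(files[1]), "truth.json")))
})

test_that("planted treated excess appears only in treated replicates", {
  g <- simulate_genome(5000, seed = 25)$genome
  truth <- sim_truth(data.frame(contig = "sim", position = 2500L,
                                excess = 20),
                     background_rate = 0, n_treated = 3L, n_mock = 3L,
                     seed = 26)
  sim <- simulate_site_seq(g, truth, out_dir = tempfile("sp"))
  t_at_site <- vapply(sim$tracks[1:3],
                      function(t) t$counts$sim[2501], integer(1))
  m_total <- vapply(sim$tracks[4:6],
                    function(t) sum(t$counts$sim), numeric(1))
  expect_true(all(t_at_site >= 10L))  # Poisson(20) essentially never < 10
  expect_true(all(m_total == 0))
  # with no background, treated reads sit exactly at the site
  expect_equal(vapply(sim$tracks[1:3], function(t) sum(t$counts$sim),
                      numeric(1)), as.numeric(t_at_site))
})

test_that("zero-rate simulation yields empty files handled as empty tracks", {
  g <- simulate_genome(3000, seed = 27)$genome
  truth <- sim_truth(background_rate = 0, n_treated = 1L, n_mock = 1L,
                     seed = 28)
  sim <- simulate_site_seq(g, truth, out_dir = tempfile("z"))
  expect_equal(sim$tracks[[1]]$library_size, 0)
  expect_warning(tr <- extract_r1_ends(sim$treated[1], g, "t", "treated"),
                 "zeros")
  expect_equal(tr$library_size, 0)
})

test_that("planted motif positions are recoverable by scanning", {
  sg <- simulate_genome(5000, n_planted_motifs = 6L, motif = "RAWTSGAAC",
                        seed = 29)
  expect_equal(nrow(sg$truth), 6L)
  hits <- scan_iupac(get_sequence(sg$genome, "sim", 0, 5000), "RAWTSGAAC")
  expect_true(all(sg$truth$position %in% hits$offset))
  expect_error(simulate_genome(100, n_planted_motifs = 5L,
                               motif = "RAWTSGAAC"), "too short")
})

test_that("neighborhood enrichment factor shapes the density difference", {
  null_sim <- simulate_neighborhood(150, enrichment = 1, seed = 31)
  d0 <- do.call(rbind, lapply(null_sim$annotations, trna_density))
  expect_lt(abs(mean(d0$difference)), 2e-4)

  strong <- simulate_neighborhood(300, enrichment = 50,
                                  background_rate = 1e-4, seed = 32)
  nt <- neighborhood_table(strong$annotations, n_boot = 500, seed = 33)
  expect_lt(nt$wilcoxon$p_value, 0.05)

  none <- simulate_neighborhood(50, enrichment = 0, seed = 34)
  d <- do.call(rbind, lapply(none$annotations, trna_density))
  # proximal placements beyond boundary spillover are suppressed
  expect_lte(mean(d$proximal_density > 0), 0.3)
})

test_that("null neighborhood p-values show no systematic rejection", {
  rejections <- 0L
  for (s in 1:15) {
    sim <- simulate_neighborhood(40, enrichment = 1, seed = 400 + s)
    nt <- suppressMessages(
      neighborhood_table(sim$annotations, n_boot = 50, seed = s))
    if (!is.null(nt$wilcoxon) && nt$wilcoxon$p_value < 0.05) {
      rejections <- rejections + 1L
    }
  }
  # nominal 5% level: 15 null datasets should essentially never reject
  # more than a third of the time
  expect_lte(rejections, 5L)
})
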
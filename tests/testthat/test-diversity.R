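test_that("allele frequencies follow the called-genotype rule", {
  gm <- toy_gm(cbind(c(0, 1, 2), c(2, 2, 2), c(0, 1, 2)))
  gm$G[3, 3] <- NA_integer_
  p <- allele_frequency(gm)
  expect_equal(unname(p), c(0.5, 1.0, 0.25))
  gm$G[, 2] <- NA_integer_
  expect_true(is.na(allele_frequency(gm)[2]))
})

test_that("closed-form diversity values are reproduced", {
  # p = 0.5: He = Nei = PIC(paper) = 0.5, PIC(botstein) = 0.375
  gm <- toy_gm(cbind(c(0, 0, 2, 2), c(0, 1, 1, 2)))
  ld <- locus_diversity(gm)
  expect_equal(ld$he, c(0.5, 0.5))
  expect_equal(ld$nei, ld$he)
  expect_equal(ld$pic, c(0.5, 0.5))
  expect_equal(locus_diversity(gm, pic_variant = "botstein")$pic,
               c(0.375, 0.375))
  expect_equal(ld$ho, c(0, 0.5))
  # p = 0.1 -> he 0.18, maf 0.1
  gm2 <- toy_gm(matrix(c(1, rep(0, 4)), ncol = 1))
  ld2 <- locus_diversity(gm2)
  expect_equal(ld2$he, 2 * 0.1 * 0.9)
  expect_equal(ld2$maf, 0.1)
  # monomorphic locus: all diversity statistics zero, not an error
  gm3 <- toy_gm(matrix(0L, 4, 1))
  ld3 <- locus_diversity(gm3)
  expect_equal(unlist(ld3[, c("ho", "he", "nei", "pic")]),
               c(ho = 0, he = 0, nei = 0, pic = 0))
})

test_that("diversity statistics match a brute-force recount", {
  set.seed(31)
  for (rep in 1:25) {
    gm <- random_gm(12, 30, miss = 0.2)
    for (variant in c("paper", "botstein")) {
      got <- locus_diversity(gm, pic_variant = variant)
      want <- naive_locus_stats(gm$G, variant)
      ok <- colSums(!is.na(gm$G)) > 0
      for (col in c("p_alt", "maf", "ho", "he", "nei", "pic")) {
        expect_equal(got[[col]][ok], want[[col]][ok], tolerance = 1e-12)
      }
    }
    # biallelic identities: nei = he, pic_botstein <= pic_paper <= he
    got <- locus_diversity(gm)
    bot <- locus_diversity(gm, pic_variant = "botstein")
    expect_equal(got$nei, got$he)
    expect_true(all(bot$pic <= got$pic + 1e-15, na.rm = TRUE))
    expect_true(all(got$pic <= got$he + 1e-15, na.rm = TRUE))
  }
})

test_that("population summaries are unweighted means and deterministic", {
  gm <- toy_gm(cbind(c(0, 1, 1, 2), c(1, 1, 0, 0)))
  pm <- data.frame(sample = gm$samples, population = "P")
  ps <- population_summary(gm, pm)
  ld <- locus_diversity(gm)
  expect_equal(ps$he, mean(ld$he))
  expect_equal(ps$ho, mean(ld$ho))
  expect_identical(population_summary(gm, pm), ps)
  expect_error(population_summary(gm, data.frame(sample = "zz",
                                                 population = "Q")),
               "no mapped")
})

test_that("observed tracks expected heterozygosity under Hardy-Weinberg", {
  set.seed(32)
  loci <- simulate_loci(c(chr1 = 5e6), 10000)
  gm <- simulate_panel(runif(10000, 0.05, 0.95), loci, 200, "H")
  pm <- data.frame(sample = gm$samples, population = "H")
  ps <- population_summary(gm, pm)
  expect_lt(abs(ps$ho - ps$he), 0.01)
})

test_that("windowed pi matches hand evaluation and tiling convention", {
  # single site, genotypes {0,2}: site pi = 2*2*2/(4*3) = 2/3
  gm <- geno_matrix(matrix(c(0L, 2L), 2, 1),
                    data.frame(chrom = "chr1", pos = 500, ref = "A",
                               alt = "G"))
  win <- windowed_pi(gm, window = 1000, step = 1000,
                     chrom_lengths = c(chr1 = 1000))
  expect_equal(win$pi_per_bp, (2 / 3) / 1000)
  expect_equal(win$n_variant_sites, 1)
  # window tiling: 100 kb chromosome, 50 kb window, 10 kb step
  tw <- tile_windows(c(chr1 = 100000), 50000, 10000)
  expect_equal(tw$start, seq(1, 90001, by = 10000))
  expect_equal(tw$end[1], 50000)
  expect_equal(tw$end[nrow(tw)], 100000)
  # empty window
  win2 <- windowed_pi(gm, window = 1000, step = 1000,
                      chrom_lengths = c(chr1 = 3000))
  expect_equal(win2$pi_per_bp[2:3], c(0, 0))
  expect_error(tile_windows(c(chr1 = 1000), 100, 200), "window")
})

test_that("windowed pi is near-unbiased for 2p(1-p) under HWE", {
  set.seed(33)
  p <- runif(5000, 0.1, 0.9)
  loci <- simulate_loci(c(chr1 = 5e6), 5000)
  gm <- simulate_panel(p, loci, 200, "H")
  win <- windowed_pi(gm, window = 50000, step = 50000)
  got <- sum(win$pi_per_bp * 50000)  # total pairwise diversity
  want <- sum(2 * p * (1 - p))
  expect_lt(abs(got - want) / want, 0.02)
  # and per-site values match the pair-enumeration oracle exactly
  gm_small <- random_gm(8, 20, miss = 0.2)
  win_s <- windowed_pi(gm_small, window = 100000, step = 100000,
                       chrom_lengths = c(chr1 = 100000))
  expect_equal(win_s$pi_per_bp * 100000,
               sum(naive_site_pi(gm_small$G)), tolerance = 1e-12)
})

test_that("sequential filters reproduce the hand-derived survivor set", {
  gm <- filter_fixture()
  res <- filter_loci(gm, min_depth = 4, max_missing = 0.3,
                     min_maf = 0.2, min_site_quality = 20)
  expect_equal(res$report$n_loci, c(10, 10, 9, 8, 5))
  expect_equal(res$gm$loci$pos, c(100, 300, 800, 900, 1000))
  # boundary behaviour: depth 4, qual 20 are kept (>= thresholds)
  expect_true(900 %in% res$gm$loci$pos)
  expect_true(1000 %in% res$gm$loci$pos)
  # disabling every step leaves the matrix unchanged
  same <- filter_loci(gm, min_depth = NULL, max_missing = NULL,
                      min_maf = NULL, min_site_quality = NULL)
  expect_identical(same$gm$G, gm$G)
})

test_that("filtering is idempotent", {
  set.seed(34)
  for (rep in 1:5) {
    gm <- random_gm(15, 40, miss = 0.25)
    gm$D <- matrix(sample(0:12, 15 * 40, replace = TRUE), 15, 40)
    gm$D[is.na(gm$G)] <- 0L
    dimnames(gm$D) <- dimnames(gm$G)
    once <- filter_loci(gm)$gm
    twice <- filter_loci(once)$gm
    expect_identical(twice$G, once$G)
    expect_equal(twice$loci, once$loci)
  }
})

test_that("dataset merging intersects loci and concatenates samples", {
  la <- data.frame(chrom = "chr1", pos = c(100, 200), ref = "A",
                   alt = "G", stringsAsFactors = FALSE)
  lb <- data.frame(chrom = "chr1", pos = c(200, 300), ref = "A",
                   alt = "G", stringsAsFactors = FALSE)
  a <- geno_matrix(matrix(0:1, 1, 2), la, samples = "x1")
  b <- geno_matrix(matrix(c(2L, 1L), 1, 2), lb, samples = "y1")
  m <- merge_datasets(a, b)
  expect_equal(m$loci$pos, 200)
  expect_equal(unname(m$G[, 1]), c(1L, 2L))
  expect_equal(m$samples, c("x1", "y1"))
  # allele conflict at a shared position is an error, never a flip
  lb2 <- lb
  lb2$ref <- c("G", "A")
  lb2$alt <- c("A", "G")
  b2 <- geno_matrix(matrix(c(2L, 1L), 1, 2), lb2, samples = "y1")
  expect_error(merge_datasets(a, b2), "conflicting")
  # duplicate sample ids across inputs
  b3 <- geno_matrix(matrix(c(2L, 1L), 1, 2), lb, samples = "x1")
  expect_error(merge_datasets(a, b3), "duplicate sample")
  # self-merge with renamed samples doubles n, keeps m
  a2 <- a
  a2 <- geno_matrix(a$G, a$loci, samples = "x2")
  m2 <- merge_datasets(a, a2)
  expect_equal(dim(m2$G), c(2L, 2L))
})
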
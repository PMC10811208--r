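test_that("p-distance follows its definition with pairwise deletion", {
  gm <- toy_gm(rbind(c(0, 1), c(1, 2), c(0, 1)))
  d <- p_distance(gm)
  expect_equal(d["S1", "S2"], (1 + 1) / 4)
  expect_equal(d["S1", "S3"], 0)
  expect_equal(diag(d), c(S1 = 0, S2 = 0, S3 = 0))
  gm2 <- toy_gm(rbind(rep(0, 5), rep(2, 5)))
  expect_equal(p_distance(gm2)[1, 2], 1.0)
  # pairwise deletion
  gm3 <- toy_gm(rbind(c(0, 2, NA), c(2, NA, 0)))
  expect_equal(p_distance(gm3)[1, 2], 2 / 2)
  gm4 <- toy_gm(rbind(c(0, NA), c(NA, 0)))
  expect_error(p_distance(gm4), "share no called loci")
})

test_that("neighbor joining solves the additive 4-taxon case by hand", {
  d <- matrix(4, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 2
  d["C", "D"] <- d["D", "C"] <- 2
  diag(d) <- 0
  tree <- neighbor_joining(d)
  # AB|CD split: external branches 1,1,1,1; additivity forces the
  # internal branch to (4 - 1 - 1 - 1 - 1)/... = 2 (d(A,C) = 1 + 2 + 1)
  expect_equal(path_length_dist(tree)[rownames(d), colnames(d)], d)
  el <- sort(tree$edge.length)
  expect_equal(el, c(1, 1, 1, 1, 2))
  # taxon-order permutation leaves the unrooted topology unchanged
  perm <- c(3, 1, 4, 2)
  tree_p <- neighbor_joining(d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(tree, tree_p)), 0)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("neighbor joining exactly recovers random additive trees", {
  set.seed(41)
  for (rep in 1:20) {
    nt <- sample(4:8, 1)
    ref <- ape::rtree(nt, br = function(n) runif(n, 0.1, 2))
    d <- path_length_dist(ape::unroot(ref))
    tree <- neighbor_joining(d)
    expect_equal(path_length_dist(tree)[rownames(d), colnames(d)], d,
                 tolerance = 1e-10)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ref), tree)), 0)
  }
})

test_that("bootstrap supports are frequencies of bipartitions", {
  set.seed(42)
  loci <- simulate_loci(c(chr1 = 1e6), 1000)
  f <- simulate_ancestral_freqs(runif(1000, 0.1, 0.9), 0.3)
  gm <- merge_datasets(simulate_panel(f[1, ], loci, 4, "A"),
                       simulate_panel(f[2, ], loci, 4, "B"))
  bs <- bootstrap_support(gm, n_reps = 100)
  expect_true(all(bs$support >= 0 & bs$support <= 1))
  split_support <- support_for_split(bs, paste0("A", sprintf("%03d", 1:4)))
  expect_gte(split_support, 0.95)
  bs1 <- bootstrap_support(gm, n_reps = 1, seed = 5)
  expect_true(all(bs1$support %in% c(0, 1)))
})

test_that("outgroup rooting places the root on the outgroup edge", {
  d <- matrix(4, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 2
  d["C", "D"] <- d["D", "C"] <- 2
  diag(d) <- 0
  tree <- neighbor_joining(d)
  rooted <- root_with_outgroup(tree, "D")
  expect_true(ape::is.rooted(rooted))
  # D alone on one side of the root
  kids <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1, 2]
  tipsets <- lapply(kids, function(k) {
    if (k <= ape::Ntip(rooted)) rooted$tip.label[k]
    else ape::extract.clade(rooted, k)$tip.label
  })
  expect_true(any(vapply(tipsets, function(s) identical(s, "D"),
                         logical(1))))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(rooted), tree)), 0)
  expect_error(root_with_outgroup(tree, "Z"), "not a tip")
})

test_that("GRM has unit diagonal and zero off-diagonal under HWE", {
  set.seed(43)
  loci <- simulate_loci(c(chr1 = 5e6), 10000)
  gm <- simulate_panel(runif(10000, 0.1, 0.9), loci, 200, "H")
  K <- grm(gm)
  expect_equal(K, t(K))
  expect_lt(abs(mean(K[upper.tri(K)])), 0.02)
  expect_lt(abs(mean(diag(K)) - 1), 0.05)
  # duplicated individual: relationship ~ its diagonal value
  gm2 <- gm_subset(gm, samples = 1:20)
  gm2$G[2, ] <- gm2$G[1, ]
  gm2 <- filter_loci(gm2, min_depth = NULL, max_missing = NULL,
                     min_site_quality = NULL, min_maf = 0.05)$gm
  K2 <- grm(gm2)
  expect_lt(abs(K2[1, 2] - K2[1, 1]), 0.05)
  gm3 <- toy_gm(rbind(c(0, 0), c(0, 0), c(0, 2)))
  expect_error(grm(gm3), "monomorphic")
})

test_that("PCA axes are ordered, centered, and separate diverged groups", {
  # identity matrix: all variance proportions equal 1/n
  pc <- pca_grm(diag(6), 6)
  expect_equal(pc$varprop, rep(1 / 6, 6))
  set.seed(44)
  loci <- simulate_loci(c(chr1 = 2e6), 3000)
  f <- simulate_ancestral_freqs(runif(3000, 0.1, 0.9), 0.1)
  gm <- merge_datasets(simulate_panel(f[1, ], loci, 50, "A"),
                       simulate_panel(f[2, ], loci, 50, "B"))
  keep <- filter_loci(gm, min_depth = NULL, max_missing = NULL,
                      min_site_quality = NULL, min_maf = 0.01)$gm
  pc <- pca_grm(grm(keep), 3)
  a <- pc$coords[1:50, 1]
  b <- pc$coords[51:100, 1]
  expect_true(max(a) < min(b) || min(a) > max(b))
  # centering contract on complete data
  expect_lt(abs(mean(pc$coords[, 1])), 1e-10)
  expect_lt(abs(mean(pc$coords[, 2])), 1e-10)
  expect_true(all(diff(pc$varprop) <= 1e-12))
})

test_that("admixture EM honours its invariants and the K=1 closed form", {
  set.seed(45)
  gm <- random_gm(20, 100, miss = 0.1)
  gm <- filter_loci(gm, min_depth = NULL, max_missing = NULL,
                    min_site_quality = NULL, min_maf = 0.01)$gm
  fit1 <- admixture_fit(gm, 1)
  expect_equal(unname(fit1$Q[, 1]), rep(1, 20))
  expect_equal(unname(fit1$F[1, ]),
               unname(pmin(pmax(allele_frequency(gm), 1e-6), 1 - 1e-6)))
  fit2 <- admixture_fit(gm, 2, seed = 1, max_iter = 50)
  expect_true(all(diff(fit2$loglik) > -1e-6))
  expect_lt(max(abs(rowSums(fit2$Q) - 1)), 1e-9)
  expect_error(admixture_fit(gm, 21), "exceeds")
})

test_that("admixture EM recovers Q on diverged panels", {
  set.seed(46)
  loci <- simulate_loci(c(chr1 = 2e6), 2000)
  f <- simulate_ancestral_freqs(runif(2000, 0.1, 0.9), 0.3)
  gm <- merge_datasets(simulate_panel(f[1, ], loci, 30, "A"),
                       simulate_panel(f[2, ], loci, 30, "B"))
  fit <- align_ancestries(admixture_fit(gm, 2, seed = 2), f)
  q_true <- c(rep(1, 30), rep(0, 30))
  expect_lt(mean(abs(fit$Q[, 1] - q_true)), 0.02)
})

test_that("parameter recovery degrades as simulated divergence shrinks", {
  set.seed(47)
  err_at <- function(F_div) {
    loci <- simulate_loci(c(chr1 = 2e6), 1500)
    f <- simulate_ancestral_freqs(runif(1500, 0.1, 0.9), F_div)
    gm <- merge_datasets(simulate_panel(f[1, ], loci, 25, "A"),
                         simulate_panel(f[2, ], loci, 25, "B"))
    fit <- align_ancestries(admixture_fit(gm, 2, seed = 3,
                                          n_restarts = 2), f)
    mean(abs(fit$Q[, 1] - c(rep(1, 25), rep(0, 25))))
  }
  errs <- vapply(c(0.3, 0.1, 0.02), err_at, numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("cross-validation error is non-negative and picks sensible K", {
  set.seed(48)
  loci <- simulate_loci(c(chr1 = 1e6), 800)
  f <- simulate_ancestral_freqs(runif(800, 0.1, 0.9), 0.3)
  gm <- merge_datasets(simulate_panel(f[1, ], loci, 20, "A"),
                       simulate_panel(f[2, ], loci, 20, "B"))
  cv <- admixture_cv(gm, K_range = 1:2, folds = 3, seed = 4,
                     n_restarts = 1, max_iter = 80)
  expect_true(all(cv$cv$cv_error >= 0))
  expect_lt(cv$cv$cv_error[2], cv$cv$cv_error[1])
})

test_that("local ancestry posteriors are proper and symmetric when uninformative", {
  set.seed(49)
  loci <- simulate_loci(c(chr1 = 1e6), 300)
  f <- runif(300, 0.2, 0.8)
  p1 <- simulate_panel(f, loci, 30, "A")
  p2 <- simulate_panel(f, loci, 30, "B")
  # force *identical* panel frequencies: same genotypes in both panels
  p2$G <- p1$G
  q <- simulate_panel(f, loci, 5, "Q")
  la <- local_ancestry(q, p1, p2, prior = 0.5)
  sums <- apply(la$posterior, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  # no information: posterior equals the diploid prior at every locus
  expect_lt(max(abs(la$posterior[, , 1] - 0.25)), 1e-9)
  expect_lt(max(abs(la$posterior[, , 2] - 0.5)), 1e-9)
})

test_that("local ancestry recovers pure and admixed ancestry", {
  set.seed(50)
  loci <- simulate_loci(c(chr1 = 2e6, chr2 = 2e6), 2000)
  f <- simulate_ancestral_freqs(runif(2000, 0.1, 0.9), 0.3)
  p1 <- simulate_panel(f[1, ], loci, 30, "A")
  p2 <- simulate_panel(f[2, ], loci, 30, "B")
  pure <- simulate_panel(f[1, ], loci, 5, "Q")
  la <- local_ancestry(pure, p1, p2)
  expect_gte(mean(la$q_hat), 0.95)
  adm <- simulate_admixed_cohort(f, loci, 10, beta_shapes(0.5, 8),
                                 gen_since_admix = 10)
  la2 <- local_ancestry(adm$gm, p1, p2, gen_since_admix = 10)
  expect_lt(mean(abs(la2$q_hat - adm$truth$q_true)), 0.03)
  acc <- mean(la2$hard_call == adm$truth$dosage)
  expect_gte(acc, 0.90)
  # order invariance of the population summary
  pm <- data.frame(sample = adm$gm$samples, population = "X")
  gs <- global_ancestry_summary(la2, pm)
  expect_equal(gs$prop_anc1 + gs$prop_anc2, 1)
  perm <- sample(length(la2$samples))
  la_perm <- la2
  la_perm$samples <- la2$samples[perm]
  la_perm$q_hat <- la2$q_hat[perm]
  expect_equal(global_ancestry_summary(la_perm, pm)$prop_anc1,
               gs$prop_anc1)
})

test_that("local-ancestry hard-call accuracy degrades with divergence", {
  set.seed(51)
  acc_at <- function(F_div) {
    loci <- simulate_loci(c(chr1 = 2e6), 1200)
    f <- simulate_ancestral_freqs(runif(1200, 0.1, 0.9), F_div)
    p1 <- simulate_panel(f[1, ], loci, 30, "A")
    p2 <- simulate_panel(f[2, ], loci, 30, "B")
    adm <- simulate_admixed_cohort(f, loci, 8, beta_shapes(0.5, 8))
    la <- local_ancestry(adm$gm, p1, p2)
    mean(la$hard_call == adm$truth$dosage)
  }
  accs <- vapply(c(0.3, 0.1, 0.02), acc_at, numeric(1))
  expect_true(all(diff(accs) < 0))
})

test_that("PC1 correlates with true ancestry in an admixed cohort", {
  set.seed(52)
  loci <- simulate_loci(c(chr1 = 2e6, chr2 = 2e6), 3000)
  f <- simulate_ancestral_freqs(runif(3000, 0.1, 0.9), 0.2)
  adm <- simulate_admixed_cohort(f, loci, 60, beta_shapes(0.5, 2))
  keep <- filter_loci(adm$gm, min_depth = NULL, max_missing = NULL,
                      min_site_quality = NULL, min_maf = 0.05)$gm
  pc <- pca_grm(grm(keep), 2)
  expect_gte(abs(cor(pc$coords[, 1], adm$truth$q_true)), 0.9)
})
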
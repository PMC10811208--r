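# Shared fixtures and independent brute-force oracles. The oracles
# recompute every quantity by naive enumeration, never through the
# package's own vectorized paths.

# Quick locus table: evenly spaced positions on one chromosome.
toy_loci <- function(m, chrom = "chr1", start = 100, by = 100,
                     qual = 30) {
  data.frame(chrom = chrom, pos = seq(start, by = by, length.out = m),
             ref = "A", alt = "G", qual = qual,
             stringsAsFactors = FALSE)
}

toy_gm <- function(G, qual = 30, D = NULL, ...) {
  G <- as.matrix(G)
  geno_matrix(G, toy_loci(ncol(G), qual = qual), D = D, ...)
}

random_gm <- function(n, m, miss = 0.1) {
  G <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  G[matrix(runif(n * m) < miss, n, m)] <- NA_integer_
  toy_gm(G)
}

# Naive per-locus statistics by explicit loops over genotypes.
naive_locus_stats <- function(G, variant = "paper") {
  m <- ncol(G)
  out <- data.frame(p_alt = numeric(m), maf = numeric(m),
                    ho = numeric(m), he = numeric(m), nei = numeric(m),
                    pic = numeric(m))
  for (l in seq_len(m)) {
    g <- G[, l]
    g <- g[!is.na(g)]
    if (length(g) == 0) {
      out[l, ] <- NA_real_
      next
    }
    n_alt <- 0
    n_het <- 0
    for (x in g) {
      n_alt <- n_alt + x
      if (x == 1) n_het <- n_het + 1
    }
    p <- n_alt / (2 * length(g))
    f <- c(p, 1 - p)
    nei <- 1 - sum(f^2)
    out$p_alt[l] <- p
    out$maf[l] <- min(f)
    out$ho[l] <- n_het / length(g)
    out$he[l] <- 2 * p * (1 - p)
    out$nei[l] <- nei
    out$pic[l] <- if (variant == "paper") nei else
      nei - 2 * p^2 * (1 - p)^2
  }
  out
}

# Naive per-site pi: enumerate every unordered pair of called alleles
# and count the differing pairs.
naive_site_pi <- function(G) {
  vapply(seq_len(ncol(G)), function(l) {
    g <- G[, l]
    alleles <- unlist(lapply(g[!is.na(g)], function(x) {
      switch(as.character(x), "0" = c(0L, 0L), "1" = c(0L, 1L),
             "2" = c(1L, 1L))
    }))
    cc <- length(alleles)
    if (cc < 2) return(0)
    diff_pairs <- 0
    total <- 0
    for (i in seq_len(cc - 1)) for (j in (i + 1):cc) {
      total <- total + 1
      if (alleles[i] != alleles[j]) diff_pairs <- diff_pairs + 1
    }
    diff_pairs / total * 1  # mean pairwise difference at this site
  }, numeric(1))
}

# Path-length (patristic) distance matrix of a phylo, by summing branch
# lengths along tip-to-tip paths on the unrooted graph.
path_length_dist <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  d <- matrix(NA_real_, nt, nt, dimnames = list(tree$tip.label,
                                                tree$tip.label))
  for (s in seq_len(nt)) {
    dist <- rep(Inf, nn); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][k, 1]; w <- adj[[v]][k, 2]
        if (dist[v] + w < dist[u] - 1e-15) {
          dist[u] <- dist[v] + w
          queue <- c(queue, u)
        }
      }
    }
    d[s, ] <- dist[seq_len(nt)]
  }
  diag(d) <- 0
  d
}

# Bootstrap support attached to a given tip bipartition (or its
# complement); NA when the reference tree has no such edge.
support_for_split <- function(bsres, tips) {
  pp <- ape::prop.part(bsres$tree)
  labs <- attr(pp, "labels")
  tips <- sort(tips)
  for (k in seq_along(pp)) {
    clade <- sort(labs[pp[[k]]])
    comp <- sort(setdiff(labs, clade))
    if (identical(clade, tips) || identical(comp, tips)) {
      return(bsres$support[k])
    }
  }
  NA_real_
}

# Hand-built 4x4-sample, 10-locus fixture for the sequential filters,
# with the survivor set derived on paper (see test-diversity.R).
filter_fixture <- function() {
  G <- rbind(
    c(0, 1, 1, 2, 0, 0, 2, 0,  1, 0),
    c(1, 1, 1, 0, 0, 0, 2, 1,  1, 2),
    c(1, 2, 0, 1, 0, 0, 1, 2,  0, 0),
    c(2, 2, 2, 2, 0, 1, 2, NA, 2, 2))
  D <- rbind(
    c(10,  3, 10, 10, 10, 10, 10, 10, 4, 10),
    c(10,  3, 10, 10, 10, 10, 10, 10, 4, 10),
    c(10, 10,  3, 10, 10, 10, 10, 10, 4, 10),
    c(10, 10, 10, 10, 10, 10, 10,  0, 4, 10))
  qual <- c(30, 30, 30, 10, 30, 30, 30, 30, 30, 20)
  toy_gm(G, qual = qual, D = D)
}

# Hand-built 10-sample, 8-locus fixture for core-panel selection; one
# gene at chr1:1001-2000 (+ strand), flank 5 kb.
core_panel_fixture <- function() {
  half <- function(p) {  # 10 genotypes with ALT frequency p
    n_alt <- round(20 * p)
    g <- c(rep(2, n_alt %/% 2), if (n_alt %% 2) 1, integer(0))
    c(g, rep(0, 10 - length(g)))
  }
  G <- cbind(
    C1 = c(rep(0, 5), rep(2, 5)),      # genic, p=0.5       -> survives
    C2 = half(0.25),                   # genic, PIC 0.375   -> drop @pic
    C3 = c(rep(0, 5), rep(2, 5)),      # intergenic         -> drop @location
    C4 = c(rep(0, 5), rep(2, 5)),      # upstream           -> survives
    C5 = c(rep(0, 5), rep(2, 5)),      # downstream         -> survives
    C6 = c(0, 1, 2, 0, rep(NA, 6)),    # 40% called         -> drop @completeness
    C7 = c(rep(0, 5), rep(2, 5)),      # all depth 3        -> drop @completeness
    C8 = rep(0, 10))                   # monomorphic        -> drop @maf
  D <- matrix(10L, 10, 8)
  D[, 7] <- 3L
  D[is.na(G)] <- 0L
  # positions: C1=1500 C2=1600 C3=9000 C4=500 C5=2500 C6=1700 C7=1800 C8=1900
  loci <- data.frame(chrom = "chr1",
                     pos = c(1500, 1600, 9000, 500, 2500, 1700, 1800,
                             1900),
                     ref = "A", alt = "G", qual = 30,
                     stringsAsFactors = FALSE)
  o <- order(loci$pos)
  gm <- geno_matrix(G[, o], loci[o, ], D = D[, o],
                    samples = sprintf("S%02d", 1:10))
  gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000),
                                 strand = "+", name = "gene_1")
  list(gm = gm, gene = gene,
       survivors = c("chr1:1500", "chr1:500", "chr1:2500"))
}
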
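#' Simulation configuration for a two-ancestry crossbred system
#'
#' Parameterizes the synthetic study system: two ancestral cattle-like
#' populations diverged under the Balding-Nichols model, a crossbred
#' cohort with Beta-distributed per-individual ancestry proportions and
#' recombination-scale ancestry tracts, a second cohort of near-total
#' single-ancestry makeup, platform effects (high-missingness
#' reduced-representation vs low-missingness whole-genome marker sets
#' with partial locus overlap), per-genotype depth, and implanted
#' low-diversity/high-differentiation sweep regions.
#'
#' @param n_loci number of biallelic SNP loci
#' @param chrom_lengths named vector of chromosome lengths (bp)
#' @param p_anc_range range for ancestral base allele frequencies
#' @param fst_divergence Balding-Nichols divergence F in (0,1)
#' @param n_panel1,n_panel2 sizes of the two ancestral reference panels
#' @param n_admixed size of the crossbred cohort
#' @param n_admixed2 size of the near-single-ancestry cohort
#' @param mean_admix target mean ancestry-1 proportion of the crossbred
#'   cohort (ancestry 1 is the first panel's lineage)
#' @param admix_conc concentration (a+b) of the Beta law for individual
#'   ancestry proportions
#' @param mean_admix2,admix_conc2 same for the second cohort
#' @param gen_since_admix generations since admixture G (tract scale)
#' @param recomb_rate Morgans per bp (uniform genetic map)
#' @param miss_rate_slaf,miss_rate_wgs per-genotype missingness of the
#'   two platforms
#' @param depth_mean expected reads per called genotype
#' @param locus_overlap fraction of loci present on each platform's
#'   marker set (sets give partial overlap)
#' @param sweep_regions list of `list(chrom, start, end, target)` regions
#'   pushed toward fixation in the target population
#' @param seed integer master seed
#' @return a `sim_config` list
#' @export
sim_config <- function(n_loci = 5000,
                       chrom_lengths = c(chr1 = 2.5e6, chr2 = 2.5e6,
                                         chr3 = 2.5e6, chr4 = 2.5e6),
                       p_anc_range = c(0.05, 0.95),
                       fst_divergence = 0.2,
                       n_panel1 = 30, n_panel2 = 30,
                       n_admixed = 50, n_admixed2 = 20,
                       mean_admix = 0.3722, admix_conc = 10,
                       mean_admix2 = 0.9514, admix_conc2 = 40,
                       gen_since_admix = 10,
                       recomb_rate = 1e-8,
                       miss_rate_slaf = 0.25, miss_rate_wgs = 0.02,
                       depth_mean = 10,
                       locus_overlap = 0.8,
                       sweep_regions = list(
                         list(chrom = "chr1", start = 1.2e6, end = 1.3e6,
                              target = "XBG")),
                       seed = 1L) {
  rates <- c(miss_rate_slaf, miss_rate_wgs, locus_overlap)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0,1]")
  if (fst_divergence <= 0 || fst_divergence >= 1) {
    stop("fst_divergence must lie in (0,1)")
  }
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (p_anc_range[1] < 0.05 - 1e-12 || p_anc_range[2] > 0.95 + 1e-12) {
    stop("p_anc_range must lie within [0.05, 0.95]")
  }
  for (sw in sweep_regions) {
    if (!sw$chrom %in% names(chrom_lengths) ||
        sw$start < 1 || sw$end > chrom_lengths[[sw$chrom]]) {
      stop("sweep region outside chromosome bounds: ", sw$chrom,
           ":", sw$start, "-", sw$end)
    }
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Beta shape parameters from a mean and concentration
#'
#' Convenience for parameterizing per-individual ancestry proportions:
#' returns `c(a, b)` with `a/(a+b) = mean` and `a + b = conc`.
#'
#' @param mean target mean in (0,1)
#' @param conc concentration a+b (larger = tighter around the mean)
#' @return length-2 shape vector for [stats::rbeta()]
#' @export
beta_shapes <- function(mean, conc) c(mean * conc, (1 - mean) * conc)

#' Draw per-ancestry allele frequencies under the Balding-Nichols model
#'
#' Each ancestry's frequency at a locus is Beta(p(1-F)/F, (1-p)(1-F)/F),
#' so its expectation is the ancestral base frequency p and its variance
#' is p(1-p)F.
#'
#' @param p_base vector of ancestral base frequencies, strictly in (0,1)
#' @param fst_divergence divergence F in (0,1)
#' @param n_pops number of descendant populations to draw (default 2)
#' @param seed optional seed
#' @return matrix with `n_pops` rows of per-locus frequencies
#' @export
simulate_ancestral_freqs <- function(p_base, fst_divergence, n_pops = 2,
                                     seed = NULL) {
  if (any(p_base <= 0 | p_base >= 1)) {
    stop("p_base entries must lie strictly in (0,1)")
  }
  if (fst_divergence <= 0 || fst_divergence >= 1) {
    stop("fst_divergence must lie in (0,1)")
  }
  if (!is.null(seed)) set.seed(seed)
  ratio <- (1 - fst_divergence) / fst_divergence
  m <- length(p_base)
  t(vapply(seq_len(n_pops), function(k) {
    stats::rbeta(m, p_base * ratio, (1 - p_base) * ratio)
  }, numeric(m)))
}

#' Place SNP loci uniformly along chromosomes
#'
#' @param chrom_lengths named lengths in bp
#' @param n_loci total loci, allocated proportionally to length
#' @param seed optional seed
#' @return locus data frame (`chrom`, `pos`, `ref`, `alt`, `qual`)
#' @export
simulate_loci <- function(chrom_lengths, n_loci, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alloc <- round(n_loci * chrom_lengths / sum(chrom_lengths))
  alloc[length(alloc)] <- n_loci - sum(alloc[-length(alloc)])
  out <- lapply(seq_along(chrom_lengths), function(i) {
    L <- chrom_lengths[[i]]
    pos <- sort(sample.int(L, alloc[i]))
    data.frame(chrom = names(chrom_lengths)[i], pos = pos,
               stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, out)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nrow(loci), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  loci$ref <- ref
  loci$alt <- unname(alt)
  loci$qual <- round(pmax(0, stats::rnorm(nrow(loci), 45, 10)), 1)
  rownames(loci) <- NULL
  loci
}

#' Simulate a pure-ancestry Hardy-Weinberg panel
#'
#' @param f per-locus allele frequencies of the ancestry
#' @param loci locus data frame
#' @param n panel size
#' @param prefix sample-name prefix
#' @param seed optional seed
#' @return a [geno_matrix()]
#' @export
simulate_panel <- function(f, loci, n, prefix = "P", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(f)
  G <- matrix(stats::rbinom(n * m, 2, rep(f, each = n)), nrow = n)
  geno_matrix(G, loci, samples = sprintf("%s%03d", prefix, seq_len(n)))
}

#' Simulate a crossbred cohort with ancestry-tract structure
#'
#' Each individual receives an ancestry proportion q drawn from a Beta
#' law. Each of its two haplotypes is a two-state Markov chain along each
#' chromosome with stationary distribution (q, 1-q) and re-draw
#' probability 1 - exp(-d G) per inter-locus genetic distance d (d =
#' physical distance times `recomb_rate`, in Morgans). Alleles are then
#' drawn Bernoulli from the tract ancestry's frequency, and the genotype
#' is the haplotype sum. The returned truth set records the per-locus
#' diploid ancestry-1 dosage; `q_true` is the realized mean dosage / 2,
#' so the truth-set identity holds exactly by construction.
#'
#' @param freqs 2 x m matrix of per-ancestry allele frequencies
#' @param loci locus data frame (sorted)
#' @param n cohort size
#' @param admix_alpha Beta shape pair c(a, b) for q (ancestry 1)
#' @param gen_since_admix generations G
#' @param recomb_rate Morgans per bp
#' @param prefix sample-name prefix
#' @param seed optional seed
#' @return list with `gm` (a [geno_matrix()]) and `truth`
#'   (`q_true`, `q_param`, `dosage` n x m matrix in \{0,1,2\})
#' @export
simulate_admixed_cohort <- function(freqs, loci, n, admix_alpha,
                                    gen_since_admix = 10,
                                    recomb_rate = 1e-8,
                                    prefix = "A", seed = NULL) {
  if (nrow(loci) == 0) stop("empty locus set")
  if (n < 1) stop("n must be >= 1")
  stopifnot(ncol(freqs) == nrow(loci))
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(loci)
  q <- stats::rbeta(n, admix_alpha[1], admix_alpha[2])
  chrom <- factor(loci$chrom, levels = unique(loci$chrom))
  # per-interval re-draw probability; 1 at chromosome boundaries
  d <- c(0, diff(loci$pos)) * recomb_rate
  new_chrom <- c(TRUE, chrom[-1] != chrom[-m])
  s <- 1 - exp(-d * gen_since_admix)
  s[new_chrom] <- 1
  G <- matrix(0L, n, m)
  dosage <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    for (h in 1:2) {
      redraw <- stats::runif(m) < s
      redraw[1] <- TRUE
      seg <- cumsum(redraw)
      anc1 <- stats::rbinom(max(seg), 1, q[i])[seg]  # 1 = ancestry 1
      f_h <- ifelse(anc1 == 1L, freqs[1, ], freqs[2, ])
      allele <- stats::rbinom(m, 1, f_h)
      G[i, ] <- G[i, ] + allele
      dosage[i, ] <- dosage[i, ] + anc1
    }
  }
  gm <- geno_matrix(G, loci, samples = sprintf("%s%03d", prefix, seq_len(n)))
  truth <- list(q_true = rowMeans(dosage) / 2, q_param = q,
                dosage = dosage, samples = gm$samples)
  list(gm = gm, truth = truth)
}

#' Implant a selective sweep into a region
#'
#' Within the region, the target samples' genotypes are redrawn from
#' frequencies pushed toward fixation (0.98 where the supplied frequency
#' is >= 0.5, else 0.02), which depresses nucleotide diversity and raises
#' differentiation there. All other loci, and all non-target samples, are
#' untouched.
#'
#' @param gm a [geno_matrix()]
#' @param freqs per-locus allele frequencies the target population was
#'   drawn from (length = loci of `gm`)
#' @param region `list(chrom, start, end)` in 1-based bp
#' @param target_rows integer or logical index of target samples
#' @param seed optional seed
#' @return the modified `geno_matrix`
#' @export
implant_sweep <- function(gm, freqs, region, target_rows, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- which(gm$loci$chrom == region$chrom &
                 gm$loci$pos >= region$start & gm$loci$pos <= region$end)
  if (!length(idx)) {
    warning("sweep region ", region$chrom, ":", region$start, "-",
            region$end, " contains no loci; matrix unchanged")
    return(gm)
  }
  rows <- seq_along(gm$samples)[target_rows]
  f_swept <- ifelse(freqs[idx] >= 0.5, 0.98, 0.02)
  nr <- length(rows)
  gm$G[rows, idx] <- matrix(
    stats::rbinom(nr * length(idx), 2, rep(f_swept, each = nr)), nrow = nr)
  gm
}

#' Apply platform missingness and sequencing depth
#'
#' Each genotype is masked missing independently with probability
#' `miss_rate`; each retained genotype gets a depth drawn from a Poisson
#' law conditioned on being at least 1. Masked genotypes get depth 0.
#'
#' @param gm a [geno_matrix()]
#' @param miss_rate per-genotype missingness probability
#' @param depth_mean Poisson mean of the (untruncated) depth law
#' @param seed optional seed
#' @return `geno_matrix` with missingness applied and a depth matrix
#' @export
apply_platform_effects <- function(gm, miss_rate, depth_mean,
                                   seed = NULL) {
  if (miss_rate < 0 || miss_rate > 1) stop("miss_rate must lie in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(gm$G); m <- ncol(gm$G)
  mask <- matrix(stats::runif(n * m) < miss_rate, n, m)
  gm$G[mask] <- NA_integer_
  # zero-truncated Poisson by inverse CDF
  u <- stats::runif(n * m, stats::dpois(0, depth_mean), 1)
  D <- matrix(stats::qpois(u, depth_mean), n, m)
  D[mask] <- 0L
  D[is.na(gm$G) & !mask] <- 0L
  gm$D <- D
  dimnames(gm$D) <- dimnames(gm$G)
  gm
}

#' Tile non-overlapping gene intervals along chromosomes
#'
#' Genes of fixed length are placed with a fixed inter-gene spacing,
#' starting at the chromosome origin, as a substrate for SNP location
#' classification and window-to-gene mapping. Strands are assigned at
#' random (seeded).
#'
#' @param chrom_lengths named lengths in bp
#' @param gene_length gene size in bp
#' @param spacing gap between consecutive genes in bp
#' @param seed optional seed (strand assignment)
#' @return a `GRanges` of genes with names `gene_<chrom>_<k>`
#' @export
simulate_gene_annotation <- function(chrom_lengths, gene_length = 20000,
                                     spacing = 30000, seed = NULL) {
  if (gene_length <= 0 || spacing <= 0) {
    stop("gene_length and spacing must be positive")
  }
  if (!is.null(seed)) set.seed(seed)
  period <- gene_length + spacing
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    if (period > L) {
      warning("gene_length + spacing exceeds length of ", ch,
              "; zero genes placed there")
      return(NULL)
    }
    starts0 <- seq.int(0, L - period, by = period)  # 0-based
    GenomicRanges::GRanges(
      ch, IRanges::IRanges(starts0 + 1, starts0 + gene_length),
      strand = sample(c("+", "-"), length(starts0), replace = TRUE),
      name = sprintf("gene_%s_%03d", ch, seq_along(starts0)))
  })
  gr <- suppressWarnings(do.call(c, out[!vapply(out, is.null, logical(1))]))
  names(gr) <- gr$name
  gr
}

#' Simulate the full two-ancestry study system
#'
#' Builds the complete synthetic analogue of the study design: two
#' diverged ancestral panels (labelled BS and KZ), a crossbred cohort
#' (XBG) with Beta-distributed ancestry proportions, a near-single-
#' ancestry cohort (XBH), implanted sweep regions, platform-specific
#' missingness/depth (SLAF-like for XBG, WGS-like for the rest) on
#' partially overlapping marker sets, and a tiled gene annotation.
#'
#' @param config a [sim_config()]
#' @return list with `gm_slaf`, `gm_wgs` (platform-specific matrices),
#'   `popmap`, `truth` (XBG and XBH truth sets), `freqs`, `loci`,
#'   `annotation`, `config`
#' @export
simulate_study <- function(config = sim_config()) {
  set.seed(config$seed)
  loci <- simulate_loci(config$chrom_lengths, config$n_loci)
  p_base <- stats::runif(config$n_loci, config$p_anc_range[1],
                         config$p_anc_range[2])
  freqs <- simulate_ancestral_freqs(p_base, config$fst_divergence)
  panel1 <- simulate_panel(freqs[1, ], loci, config$n_panel1, "BS")
  panel2 <- simulate_panel(freqs[2, ], loci, config$n_panel2, "KZ")
  adm <- simulate_admixed_cohort(
    freqs, loci, config$n_admixed,
    beta_shapes(config$mean_admix, config$admix_conc),
    config$gen_since_admix, config$recomb_rate, prefix = "XBG")
  adm2 <- simulate_admixed_cohort(
    freqs, loci, config$n_admixed2,
    beta_shapes(config$mean_admix2, config$admix_conc2),
    config$gen_since_admix, config$recomb_rate, prefix = "XBH")
  pops <- list(BS = panel1, KZ = panel2, XBG = adm$gm, XBH = adm2$gm)
  for (sw in config$sweep_regions) {
    tgt <- pops[[sw$target]]
    f_tgt <- switch(sw$target, BS = freqs[1, ], KZ = freqs[2, ],
                    # crossbred cohorts: sweep acts on the mixture freq
                    config$mean_admix * freqs[1, ] +
                      (1 - config$mean_admix) * freqs[2, ])
    pops[[sw$target]] <- implant_sweep(
      tgt, f_tgt, sw, seq_along(tgt$samples))
  }
  popmap <- do.call(rbind, lapply(names(pops), function(p) {
    data.frame(sample = pops[[p]]$samples, population = p,
               stringsAsFactors = FALSE)
  }))
  # platform marker sets with partial overlap
  m <- nrow(loci)
  slaf_loci <- sort(sample.int(m, round(config$locus_overlap * m)))
  wgs_loci <- sort(sample.int(m, round(config$locus_overlap * m)))
  bind_pops <- function(lst) {
    G <- do.call(rbind, lapply(lst, `[[`, "G"))
    geno_matrix(G, lst[[1]]$loci,
                samples = unlist(lapply(lst, `[[`, "samples")))
  }
  gm_slaf <- gm_subset(bind_pops(pops["XBG"]), loci = slaf_loci)
  gm_wgs <- gm_subset(bind_pops(pops[c("BS", "KZ", "XBH")]),
                      loci = wgs_loci)
  gm_slaf <- apply_platform_effects(gm_slaf, config$miss_rate_slaf,
                                    config$depth_mean)
  gm_wgs <- apply_platform_effects(gm_wgs, config$miss_rate_wgs,
                                   config$depth_mean)
  gm_slaf$platform <- rep("SLAF", length(gm_slaf$samples))
  gm_wgs$platform <- rep("WGS", length(gm_wgs$samples))
  annotation <- simulate_gene_annotation(config$chrom_lengths)
  list(gm_slaf = gm_slaf, gm_wgs = gm_wgs, popmap = popmap,
       truth = list(XBG = adm$truth, XBH = adm2$truth),
       freqs = freqs, loci = loci, annotation = annotation,
       config = config)
}

#' Write a cohort truth set as TSV
#'
#' Long format: one row per (sample, locus) with the true diploid
#' ancestry-1 dosage.
#'
#' @param truth truth set from [simulate_admixed_cohort()]
#' @param loci locus data frame the dosages refer to
#' @param path output path
#' @export
write_truth_tsv <- function(truth, loci, path) {
  n <- length(truth$samples)
  m <- nrow(loci)
  df <- data.frame(sample = rep(truth$samples, each = m),
                   chrom = rep(loci$chrom, n),
                   pos = rep(loci$pos, n),
                   dosage = as.vector(t(truth$dosage)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
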
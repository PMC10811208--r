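#' Per-locus allele frequency
#'
#' ALT-allele frequency over called genotypes of one population:
#' (sum of genotype codes) / (2 * number called). Missing genotypes are
#' excluded from both numerator and denominator.
#'
#' @param gm a [geno_matrix()]
#' @param rows sample index (rows) defining the population; default all
#' @return numeric vector of frequencies; `NA` where no genotype is called
#' @export
allele_frequency <- function(gm, rows = seq_along(gm$samples)) {
  G <- gm$G[rows, , drop = FALSE]
  n_called <- colSums(!is.na(G))
  p <- colSums(G, na.rm = TRUE) / (2 * n_called)
  p[n_called == 0] <- NA_real_
  p
}

#' Per-locus diversity statistics
#'
#' Observed heterozygosity Ho = n_het / n_called; expected
#' heterozygosity He = 2p(1-p); Nei's gene diversity 1 - p^2 - (1-p)^2
#' (equal to He for biallelic loci); polymorphism information content in
#' two variants — `paper`: PIC = 1 - sum(f_i^2) (the gene-diversity
#' form), `botstein`: additionally subtracting the double-heterozygote
#' term 2p^2(1-p)^2; minor-allele frequency min(p, 1-p). A monomorphic
#' locus has all diversity statistics 0.
#'
#' @param gm a [geno_matrix()]
#' @param rows sample index defining the population; default all
#' @param pic_variant `"paper"` (default) or `"botstein"`
#' @return data frame with one row per locus: `p_alt`, `maf`, `n_called`,
#'   `ho`, `he`, `nei`, `pic`, `mean_depth`
#' @export
locus_diversity <- function(gm, rows = seq_along(gm$samples),
                            pic_variant = c("paper", "botstein")) {
  pic_variant <- match.arg(pic_variant)
  G <- gm$G[rows, , drop = FALSE]
  n_called <- colSums(!is.na(G))
  p <- colSums(G, na.rm = TRUE) / (2 * n_called)
  p[n_called == 0] <- NA_real_
  ho <- colSums(G == 1L, na.rm = TRUE) / n_called
  ho[n_called == 0] <- NA_real_
  he <- 2 * p * (1 - p)
  nei <- 1 - p^2 - (1 - p)^2
  pic <- if (pic_variant == "paper") nei else nei - 2 * p^2 * (1 - p)^2
  md <- if (!is.null(gm$D)) {
    D <- gm$D[rows, , drop = FALSE]
    colMeans(ifelse(is.na(G), NA, D), na.rm = TRUE)
  } else {
    rep(NA_real_, ncol(G))
  }
  data.frame(chrom = gm$loci$chrom, pos = gm$loci$pos,
             p_alt = p, maf = pmin(p, 1 - p), n_called = n_called,
             ho = ho, he = he, nei = nei, pic = pic, mean_depth = md,
             stringsAsFactors = FALSE)
}

#' Per-population diversity summary
#'
#' Unweighted means of the per-locus statistics over loci with at least
#' one called genotype in the population — the structure of the usual
#' population-program summary tables.
#'
#' @param gm a [geno_matrix()]
#' @param popmap data frame (`sample`, `population`)
#' @param pic_variant passed to [locus_diversity()]
#' @return data frame: one row per population with mean `maf`, `ho`,
#'   `he`, `nei`, `pic` and the locus count used
#' @export
population_summary <- function(gm, popmap,
                               pic_variant = c("paper", "botstein")) {
  pic_variant <- match.arg(pic_variant)
  pops <- unique(popmap$population[popmap$sample %in% gm$samples])
  if (!length(pops)) stop("no mapped populations present in matrix")
  out <- lapply(pops, function(p) {
    rows <- pop_rows(gm, popmap, p)
    ls <- locus_diversity(gm, rows, pic_variant)
    keep <- ls$n_called >= 1
    data.frame(population = p, n_samples = length(rows),
               n_loci = sum(keep),
               maf = mean(ls$maf[keep]), ho = mean(ls$ho[keep]),
               he = mean(ls$he[keep]), nei = mean(ls$nei[keep]),
               pic = mean(ls$pic[keep]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Per-site unbiased pi: 2 * c_alt * c_ref / (c_tot * (c_tot - 1)), with
# c_tot the called allele count. 0 where fewer than 2 alleles called.
site_pi <- function(gm, rows = seq_along(gm$samples)) {
  G <- gm$G[rows, , drop = FALSE]
  c_tot <- 2 * colSums(!is.na(G))
  c_alt <- colSums(G, na.rm = TRUE)
  c_ref <- c_tot - c_alt
  pi <- ifelse(c_tot >= 2, 2 * c_alt * c_ref / (c_tot * (c_tot - 1)), 0)
  pi
}

#' Windowed nucleotide diversity
#'
#' Sums the per-site unbiased pi over each sliding window and divides by
#' the nominal window size (terminal truncated windows divide by their
#' actual span), giving per-bp diversity.
#'
#' @param gm a [geno_matrix()]
#' @param rows sample index defining the population; default all
#' @param window window size in bp
#' @param step step size in bp
#' @param chrom_lengths optional named lengths; default max position per
#'   chromosome
#' @return data frame: `chrom`, `start`, `end`, `pi_per_bp`,
#'   `n_variant_sites`
#' @export
windowed_pi <- function(gm, rows = seq_along(gm$samples),
                        window = 100000, step = 10000,
                        chrom_lengths = NULL) {
  lens <- infer_chrom_lengths(gm$loci, chrom_lengths)
  win <- tile_windows(lens, window, step)
  idx <- window_locus_index(gm$loci, win)
  sp <- site_pi(gm, rows)
  win$pi_per_bp <- vapply(seq_len(nrow(win)), function(w) {
    denom <- if (win$span[w] < window) win$span[w] else window
    sum(sp[idx[[w]]]) / denom
  }, numeric(1))
  win$n_variant_sites <- vapply(idx, function(i) sum(sp[i] > 0),
                                numeric(1))
  win$span <- NULL
  win
}

#' Sequential locus filtering
#'
#' Applies the standard post-calling filters in a fixed order: (1) mask
#' genotypes with depth below `min_depth`; (2) drop loci whose missing
#' fraction (after masking) exceeds `max_missing`; (3) drop loci with
#' site quality below `min_site_quality`; (4) drop loci with MAF below
#' `min_maf`. Each step can be disabled by passing `NULL`. The returned
#' report logs the locus count surviving each step, since the order
#' affects the per-step counts.
#'
#' @param gm a [geno_matrix()]
#' @param min_depth genotype depth threshold (needs a depth matrix)
#' @param max_missing maximum per-locus missing fraction
#' @param min_maf minimum minor-allele frequency
#' @param min_site_quality minimum per-site quality (MQ-like)
#' @return list with `gm` (filtered matrix) and `report` (data frame of
#'   per-step surviving locus counts)
#' @export
filter_loci <- function(gm, min_depth = 4, max_missing = 0.3,
                        min_maf = 0.01, min_site_quality = 20) {
  steps <- list()
  m0 <- ncol(gm$G)
  if (!is.null(min_depth)) {
    if (is.null(gm$D)) stop("depth filter requested but matrix has no depths")
    if (min_depth < 0) stop("min_depth must be >= 0")
    gm$G[!is.na(gm$G) & gm$D < min_depth] <- NA_integer_
    steps$depth_mask <- ncol(gm$G)
  }
  if (!is.null(max_missing)) {
    if (max_missing < 0 || max_missing > 1) stop("max_missing must lie in [0,1]")
    miss <- colMeans(is.na(gm$G))
    gm <- gm_subset(gm, loci = miss <= max_missing)
    steps$missingness <- ncol(gm$G)
  }
  if (!is.null(min_site_quality)) {
    q <- gm$loci$qual
    keep <- is.na(q) | q >= min_site_quality
    gm <- gm_subset(gm, loci = keep)
    steps$site_quality <- ncol(gm$G)
  }
  if (!is.null(min_maf)) {
    if (min_maf < 0 || min_maf > 0.5) stop("min_maf must lie in [0,0.5]")
    p <- allele_frequency(gm)
    maf <- pmin(p, 1 - p)
    gm <- gm_subset(gm, loci = !is.na(maf) & maf >= min_maf)
    steps$maf <- ncol(gm$G)
  }
  report <- data.frame(step = c("input", names(steps)),
                       n_loci = c(m0, unlist(steps, use.names = FALSE)))
  list(gm = gm, report = report)
}

#' Merge two genotype datasets on shared loci
#'
#' Intersects loci on (chrom, pos, ref, alt) and concatenates samples —
#' the usual way a reduced-representation and a whole-genome call set are
#' combined before re-filtering. A shared position with conflicting or
#' swapped alleles is an error, never a silent flip.
#'
#' @param gm_a,gm_b two [geno_matrix()] objects on the same reference
#'   coordinates
#' @return merged `geno_matrix`
#' @export
merge_datasets <- function(gm_a, gm_b) {
  dup <- intersect(gm_a$samples, gm_b$samples)
  if (length(dup)) {
    stop("duplicate sample ids across inputs: ",
         paste(dup, collapse = ", "))
  }
  key_a <- paste(gm_a$loci$chrom, gm_a$loci$pos)
  key_b <- paste(gm_b$loci$chrom, gm_b$loci$pos)
  shared <- intersect(key_a, key_b)
  ia <- match(shared, key_a)
  ib <- match(shared, key_b)
  conflict <- gm_a$loci$ref[ia] != gm_b$loci$ref[ib] |
    gm_a$loci$alt[ia] != gm_b$loci$alt[ib]
  if (any(conflict)) {
    stop("conflicting alleles at shared position(s): ",
         paste(utils::head(shared[conflict], 5), collapse = "; "))
  }
  a <- gm_subset(gm_a, loci = ia)
  b <- gm_subset(gm_b, loci = ib)
  D <- if (!is.null(a$D) && !is.null(b$D)) rbind(a$D, b$D) else NULL
  geno_matrix(rbind(a$G, b$G), a$loci, D = D,
              samples = c(a$samples, b$samples),
              platform = if (!is.null(a$platform) && !is.null(b$platform))
                c(a$platform, b$platform))
}
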
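#' Windowed Weir-Cockerham FST between two populations
#'
#' Per-site two-population Weir-Cockerham variance components a (among
#' populations), b (among individuals within populations) and c (within
#' individuals), computed from genotype counts with observed
#' heterozygosity and unequal sample sizes. Window FST is the weighted
#' ("ratio of sums") estimator sum(a) / sum(a + b + c) over the sites in
#' the window; negative values are retained. Sites contribute only when
#' both populations have at least 2 called genotypes; windows with no
#' contributing site are `NA`.
#'
#' @param gm a [geno_matrix()]
#' @param popmap data frame (`sample`, `population`)
#' @param popA,popB population labels
#' @param window,step window and step sizes in bp
#' @param chrom_lengths optional named chromosome lengths
#' @return data frame: `chrom`, `start`, `end`, `n_sites`, `fst`
#' @export
windowed_fst <- function(gm, popmap, popA, popB, window = 50000,
                         step = 10000, chrom_lengths = NULL) {
  ra <- pop_rows(gm, popmap, popA)
  rb <- pop_rows(gm, popmap, popB)
  comp <- fst_site_components(gm, ra, rb)
  lens <- infer_chrom_lengths(gm$loci, chrom_lengths)
  win <- tile_windows(lens, window, step)
  idx <- window_locus_index(gm$loci, win)
  win$n_sites <- vapply(idx, function(i) sum(comp$valid[i]), numeric(1))
  win$fst <- vapply(seq_len(nrow(win)), function(w) {
    i <- idx[[w]]
    i <- i[comp$valid[i]]
    if (!length(i)) return(NA_real_)
    den <- sum(comp$a[i] + comp$b[i] + comp$c[i])
    if (den == 0) return(NA_real_)
    sum(comp$a[i]) / den
  }, numeric(1))
  win$span <- NULL
  win
}

# Per-site Weir-Cockerham (1984) components for r = 2 populations,
# genotype-based. Returns vectors a, b, c and a validity flag
# (>= 2 called genotypes in each population and a polymorphic mean
# frequency).
fst_site_components <- function(gm, rows_a, rows_b) {
  count_pop <- function(rows) {
    G <- gm$G[rows, , drop = FALSE]
    n <- colSums(!is.na(G))
    p <- ifelse(n > 0, colSums(G, na.rm = TRUE) / (2 * n), NA_real_)
    h <- ifelse(n > 0, colSums(G == 1L, na.rm = TRUE) / n, NA_real_)
    list(n = n, p = p, h = h)
  }
  A <- count_pop(rows_a)
  B <- count_pop(rows_b)
  valid <- A$n >= 2 & B$n >= 2
  r <- 2
  nbar <- (A$n + B$n) / r
  nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r -
       hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!valid] <- 0; b[!valid] <- 0; cc[!valid] <- 0
  list(a = a, b = b, c = cc, valid = valid)
}

#' Z-transform a statistic over windows
#'
#' z = (x - mean) / sd with the sample standard deviation (denominator
#' n - 1), computed over the non-missing values; missing windows stay
#' missing.
#'
#' @param values numeric vector (may contain `NA`)
#' @return z-scores, same length
#' @export
z_transform <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 2) stop("z-transform needs at least 2 finite values")
  s <- stats::sd(x)
  if (s == 0) stop("degenerate scan: all window values identical")
  (values - mean(x)) / s
}

#' Log2 ratio of windowed nucleotide diversity
#'
#' log2(pi_a / pi_b) per window; `pi_a` is the comparator population and
#' `pi_b` the putatively selected one, so large positive values mark
#' diversity loss in population B. Windows where either pi is 0 (or
#' missing) are excluded from ranking (`NA`) and counted.
#'
#' @param pi_a,pi_b per-window per-bp diversity vectors, same windows
#' @return list with `log2_ratio` and `n_excluded`
#' @export
log2_pi_ratio <- function(pi_a, pi_b) {
  if (length(pi_a) != length(pi_b)) stop("window vectors differ in length")
  bad <- !is.finite(pi_a) | !is.finite(pi_b) | pi_a == 0 | pi_b == 0
  ratio <- ifelse(bad, NA_real_, log2(pi_a / pi_b))
  list(log2_ratio = ratio, n_excluded = sum(bad))
}

#' Select top-quantile intersection outlier windows
#'
#' Thresholds both statistics at their empirical (1 - top_fraction)
#' quantiles (linear interpolation) over the retained windows (both
#' statistics non-missing) and flags windows at or above both
#' thresholds.
#'
#' @param tab window table with columns `z_fst` and `log2_ratio`
#' @param top_fraction upper tail fraction (default 0.05)
#' @return `tab` with a logical `outlier` column, plus attributes
#'   `threshold_z` and `threshold_r`
#' @export
select_outliers <- function(tab, top_fraction = 0.05) {
  retained <- is.finite(tab$z_fst) & is.finite(tab$log2_ratio)
  if (sum(retained) < 20) {
    warning("fewer than 20 retained windows; quantile thresholds unstable")
  }
  tz <- stats::quantile(tab$z_fst[retained], 1 - top_fraction, names = FALSE)
  tr <- stats::quantile(tab$log2_ratio[retained], 1 - top_fraction,
                        names = FALSE)
  tab$outlier <- retained & tab$z_fst >= tz & tab$log2_ratio >= tr
  attr(tab, "threshold_z") <- tz
  attr(tab, "threshold_r") <- tr
  tab
}

#' Full two-population selective-sweep scan
#'
#' Windowed Weir-Cockerham FST and per-population pi, Z-transformation
#' of FST, log2 pi ratio (comparator A over selected B), and top-
#' quantile intersection outliers.
#'
#' @param gm a filtered [geno_matrix()]
#' @param popmap data frame (`sample`, `population`)
#' @param popA comparator population (pi numerator)
#' @param popB putatively selected population (pi denominator)
#' @param window,step window and step in bp
#' @param top_fraction outlier tail fraction
#' @param chrom_lengths optional named lengths
#' @return window table with `fst`, `z_fst`, `pi_a`, `pi_b`,
#'   `log2_ratio`, `outlier`; attributes `threshold_z`, `threshold_r`,
#'   `n_excluded`, `orientation`
#' @export
sweep_scan <- function(gm, popmap, popA, popB, window = 50000,
                       step = 10000, top_fraction = 0.05,
                       chrom_lengths = NULL) {
  fst <- windowed_fst(gm, popmap, popA, popB, window, step, chrom_lengths)
  pa <- windowed_pi(gm, pop_rows(gm, popmap, popA), window, step,
                    chrom_lengths)
  pb <- windowed_pi(gm, pop_rows(gm, popmap, popB), window, step,
                    chrom_lengths)
  stopifnot(nrow(fst) == nrow(pa), nrow(fst) == nrow(pb))
  tab <- fst
  tab$z_fst <- z_transform(tab$fst)
  tab$pi_a <- pa$pi_per_bp
  tab$pi_b <- pb$pi_per_bp
  lr <- log2_pi_ratio(tab$pi_a, tab$pi_b)
  tab$log2_ratio <- lr$log2_ratio
  tab <- select_outliers(tab, top_fraction)
  attr(tab, "n_excluded") <- lr$n_excluded
  attr(tab, "orientation") <- paste0("pi_", popA, "/pi_", popB)
  tab
}

#' Map outlier windows to SNPs and genes
#'
#' SNPs are the loci falling inside any outlier window; genes are the
#' annotation intervals overlapping any outlier window by at least 1 bp.
#' Both lists are deduplicated and sorted.
#'
#' @param tab a window table with an `outlier` column
#' @param annotation `GRanges` of genes
#' @param gm the scanned [geno_matrix()]
#' @return list with `windows` (outlier rows), `snps` (locus data
#'   frame), `genes` (character vector of gene names)
#' @export
map_windows_to_genes <- function(tab, annotation, gm) {
  out <- tab[which(tab$outlier), , drop = FALSE]
  if (nrow(out) == 0) {
    return(list(windows = out,
                snps = gm$loci[0, , drop = FALSE],
                genes = character(0)))
  }
  wg <- GenomicRanges::reduce(GenomicRanges::GRanges(
    out$chrom, IRanges::IRanges(out$start, out$end)))
  lg <- GenomicRanges::GRanges(gm$loci$chrom,
                               IRanges::IRanges(gm$loci$pos, gm$loci$pos))
  snps <- gm$loci[IRanges::overlapsAny(lg, wg), , drop = FALSE]
  hit <- IRanges::overlapsAny(annotation, wg, ignore.strand = TRUE)
  genes <- annotation$name[hit]
  if (is.null(genes)) genes <- as.character(which(hit))
  list(windows = out, snps = snps, genes = sort(unique(genes)))
}

#' Gene-set enrichment by hypergeometric / Fisher test
#'
#' For each term, the upper-tail hypergeometric probability of drawing
#' at least the observed overlap between the candidate set and the term
#' (population = background genes), or equivalently a one-sided Fisher
#' exact test on the 2x2 table; Benjamini-Hochberg step-up correction
#' over all tested terms. Terms with no background genes are skipped
#' with a warning.
#'
#' @param candidates character vector of candidate genes (subset of
#'   background)
#' @param background character vector of all annotated genes
#' @param term_map data frame (`term`, `gene`) mapping terms to
#'   background genes
#' @param method `"hypergeometric"` (default) or `"fisher"` — they agree
#'   to numerical precision
#' @return data frame: `term`, `term_size`, `overlap`, `p`, `q`
#'   (BH-adjusted), sorted by `p`
#' @export
enrichment <- function(candidates, background, term_map,
                       method = c("hypergeometric", "fisher")) {
  method <- match.arg(method)
  if (!all(candidates %in% background)) {
    stop("candidates must be a subset of the background")
  }
  N <- length(unique(background))
  n <- length(unique(candidates))
  terms <- unique(term_map$term)
  rows <- lapply(terms, function(tm) {
    genes <- intersect(unique(term_map$gene[term_map$term == tm]),
                       background)
    K <- length(genes)
    if (K == 0) {
      warning("term '", tm, "' has no background genes; skipped")
      return(NULL)
    }
    x <- length(intersect(genes, candidates))
    p <- if (method == "hypergeometric") {
      stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    } else {
      ct <- matrix(c(x, K - x, n - x, N - K - (n - x)), 2)
      stats::fisher.test(ct, alternative = "greater")$p.value
    }
    data.frame(term = tm, term_size = K, overlap = x, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(term = character(0), term_size = integer(0),
                      overlap = integer(0), p = numeric(0),
                      q = numeric(0)))
  }
  res$q <- stats::p.adjust(res$p, method = "BH")
  res[order(res$p), , drop = FALSE]
}
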
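#' Five-step core-SNP panel selection
#'
#' Sequential marker screening for a genotyping panel, with an audit
#' trail: (1) mask genotypes with depth below `min_depth` (or drop whole
#' loci containing any low-depth call when `drop_low_depth_loci`);
#' (2) drop loci genotyped in fewer than `min_completeness` of the
#' individuals; (3) drop loci with MAF below `min_maf`; (4) drop loci
#' with PIC below `min_pic` (default the gene-diversity form
#' PIC = 1 - sum(f_i^2); for biallelic loci this caps at 0.5, so
#' `min_pic = 0.4` implies MAF >= 0.2764); (5) drop loci classified
#' intergenic, keeping genic and 5 kb up/downstream loci.
#'
#' @param gm a [geno_matrix()] with depths
#' @param annotation `GRanges` of genes (used to classify loci when the
#'   matrix does not already carry location classes)
#' @param min_depth genotype depth threshold
#' @param min_completeness minimum called fraction per locus
#' @param min_maf minimum minor-allele frequency
#' @param min_pic minimum polymorphism information content
#' @param pic_variant `"paper"` (1 - sum f^2) or `"botstein"`
#' @param flank flank size for location classes (bp)
#' @param drop_low_depth_loci drop loci with any sub-threshold depth
#'   instead of masking genotypes
#' @return list with `gm` (the core panel), `report` (per-step locus
#'   counts), `panel` (per-locus table with `maf`, `pic`,
#'   `location_class`)
#' @export
select_core_snps <- function(gm, annotation, min_depth = 4,
                             min_completeness = 0.70, min_maf = 0.01,
                             min_pic = 0.4,
                             pic_variant = c("paper", "botstein"),
                             flank = 5000,
                             drop_low_depth_loci = FALSE) {
  pic_variant <- match.arg(pic_variant)
  if (is.null(gm$D) && !is.null(min_depth)) {
    stop("core-panel depth step needs a depth matrix")
  }
  steps <- data.frame(step = "input", n_loci = ncol(gm$G))
  log_step <- function(name, n) {
    steps <<- rbind(steps, data.frame(step = name, n_loci = n))
  }
  # 1. depth
  if (!is.null(min_depth)) {
    low <- !is.na(gm$G) & gm$D < min_depth
    if (drop_low_depth_loci) {
      gm <- gm_subset(gm, loci = colSums(low) == 0)
    } else {
      gm$G[low] <- NA_integer_
    }
    log_step("depth", ncol(gm$G))
  }
  # 2. completeness
  called <- colMeans(!is.na(gm$G))
  gm <- gm_subset(gm, loci = called >= min_completeness)
  log_step("completeness", ncol(gm$G))
  # 3. MAF
  p <- allele_frequency(gm)
  maf <- pmin(p, 1 - p)
  gm <- gm_subset(gm, loci = !is.na(maf) & maf >= min_maf)
  log_step("maf", ncol(gm$G))
  # 4. PIC
  ld <- locus_diversity(gm, pic_variant = pic_variant)
  gm <- gm_subset(gm, loci = !is.na(ld$pic) & ld$pic >= min_pic)
  log_step("pic", ncol(gm$G))
  # 5. location
  if (all(gm$loci$location_class == "unassigned")) {
    if (missing(annotation) || is.null(annotation)) {
      stop("location step needs a gene annotation")
    }
    gm$loci <- classify_locus_location(gm$loci, annotation, flank)
  }
  gm <- gm_subset(gm, loci = gm$loci$location_class != "intergenic")
  log_step("location", ncol(gm$G))
  ld <- locus_diversity(gm, pic_variant = pic_variant)
  panel <- data.frame(chrom = gm$loci$chrom, pos = gm$loci$pos,
                      ref = gm$loci$ref, alt = gm$loci$alt,
                      maf = ld$maf, pic = ld$pic,
                      location_class = gm$loci$location_class,
                      stringsAsFactors = FALSE)
  rownames(steps) <- NULL
  list(gm = gm, report = steps, panel = panel)
}

#' Location-class breakdown of a core panel
#'
#' Fraction of final core loci per location class; fractions sum to 1.
#'
#' @param report a [select_core_snps()] result
#' @return data frame: `location_class`, `n`, `fraction`
#' @export
panel_location_breakdown <- function(report) {
  cls <- report$panel$location_class
  if (!length(cls)) stop("no core loci in panel")
  tab <- table(cls)
  data.frame(location_class = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / length(cls),
             stringsAsFactors = FALSE)
}
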
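#' Genotype matrix container
#'
#' The central data model of the pipeline: a samples x loci matrix of
#' biallelic genotype codes counting non-reference alleles (0, 1, 2, or
#' `NA` for missing), an ordered locus table, and an optional matching
#' matrix of per-genotype sequencing depths.
#'
#' @param G integer matrix, samples in rows and loci in columns; entries
#'   in \{0, 1, 2, NA\}. Row names are taken as sample identifiers.
#' @param loci data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, and optionally `qual` (a per-site RMS-mapping-quality-like
#'   score) and `location_class`. One row per column of `G`, strictly
#'   sorted by (chrom, pos).
#' @param D optional non-negative integer matrix of per-genotype depths,
#'   same dimensions as `G`.
#' @param samples character vector of sample identifiers; defaults to
#'   `rownames(G)`.
#' @param platform optional per-sample platform tag (e.g. "SLAF", "WGS").
#'
#' @return an object of class `geno_matrix`: a list with elements `G`,
#'   `D`, `loci`, `samples`, `platform`.
#' @export
geno_matrix <- function(G, loci, D = NULL, samples = rownames(G),
                        platform = NULL) {
  G <- as.matrix(G)
  storage.mode(G) <- "integer"
  if (is.null(samples)) {
    samples <- paste0("S", seq_len(nrow(G)))
  }
  stopifnot(is.data.frame(loci))
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols)) {
    stop("loci table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"qual" %in% names(loci)) loci$qual <- rep(NA_real_, nrow(loci))
  if (!"location_class" %in% names(loci)) {
    loci$location_class <- rep("unassigned", nrow(loci))
  }
  if (nrow(loci) != ncol(G)) {
    stop("loci table has ", nrow(loci), " rows but G has ", ncol(G),
         " columns")
  }
  if (length(samples) != nrow(G)) {
    stop("sample vector length does not match rows of G")
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  bad <- !(G %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad, na.rm = TRUE)) {
    stop("genotype codes outside {0,1,2,NA}")
  }
  if (nrow(loci) > 0) {
    if (any(loci$pos < 1)) stop("locus positions must be >= 1")
    if (any(loci$ref == loci$alt)) stop("ref and alt alleles must differ")
    o <- order(loci$chrom, loci$pos)
    if (!identical(o, seq_len(nrow(loci)))) {
      stop("loci must be sorted by (chrom, pos)")
    }
    key <- paste(loci$chrom, loci$pos)
    if (anyDuplicated(key)) {
      stop("duplicate locus positions: ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    }
  }
  if (!is.null(D)) {
    D <- as.matrix(D)
    storage.mode(D) <- "integer"
    if (!identical(dim(D), dim(G))) stop("depth matrix dimensions differ from G")
    if (any(D < 0, na.rm = TRUE)) stop("depths must be non-negative")
  }
  if (!is.null(platform) && length(platform) != length(samples)) {
    stop("platform tag length does not match samples")
  }
  rownames(G) <- samples
  colnames(G) <- if (nrow(loci)) paste0(loci$chrom, ":", loci$pos)
  if (!is.null(D)) dimnames(D) <- dimnames(G)
  rownames(loci) <- NULL
  structure(list(G = G, D = D, loci = loci, samples = samples,
                 platform = platform),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", length(x$samples), "samples x", nrow(x$loci),
      "loci\n")
  miss <- if (length(x$G)) mean(is.na(x$G)) else 0
  cat("  missing genotypes:", sprintf("%.2f%%", 100 * miss),
      if (is.null(x$D)) "(no depth)" else "(with depth)", "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$G)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param gm a [geno_matrix()]
#' @param samples character vector of sample ids or logical/integer index
#' @param loci logical or integer index over locus columns
#' @return a `geno_matrix`
#' @export
gm_subset <- function(gm, samples = NULL, loci = NULL) {
  si <- seq_along(gm$samples)
  if (!is.null(samples)) {
    if (is.character(samples)) {
      si <- match(samples, gm$samples)
      if (anyNA(si)) {
        stop("unknown sample(s): ",
             paste(samples[is.na(si)], collapse = ", "))
      }
    } else {
      si <- si[samples]
    }
  }
  li <- seq_len(nrow(gm$loci))
  if (!is.null(loci)) li <- li[loci]
  geno_matrix(gm$G[si, li, drop = FALSE],
              gm$loci[li, , drop = FALSE],
              D = if (!is.null(gm$D)) gm$D[si, li, drop = FALSE],
              samples = gm$samples[si],
              platform = gm$platform[si])
}

#' Samples belonging to one population
#'
#' @param gm a [geno_matrix()]
#' @param popmap data frame with columns `sample`, `population`
#' @param pop population label
#' @return integer row indices into `gm`
#' @export
pop_rows <- function(gm, popmap, pop) {
  ids <- popmap$sample[popmap$population == pop]
  idx <- match(intersect(ids, gm$samples), gm$samples)
  if (!length(idx)) stop("population '", pop, "' has no samples in matrix")
  idx
}
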
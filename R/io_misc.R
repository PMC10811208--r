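#' Read a sample-to-population map
#'
#' Two- or three-column tab-separated file with a header row: `sample`,
#' `population`, and optionally `subgroup` (e.g. coat-colour groups).
#'
#' @param path TSV path
#' @param gm optional [geno_matrix()]; when given, every sample of the
#'   matrix must appear in the map, otherwise an error names the missing
#'   samples.
#' @return data frame with columns `sample`, `population` (and `subgroup`
#'   when present)
#' @export
read_population_map <- function(path, gm = NULL) {
  pm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(pm))) {
    stop("population map needs 'sample' and 'population' columns")
  }
  if (anyDuplicated(pm$sample)) {
    stop("samples mapped more than once: ",
         paste(unique(pm$sample[duplicated(pm$sample)]), collapse = ", "))
  }
  if (!is.null(gm)) {
    missing <- setdiff(gm$samples, pm$sample)
    if (length(missing)) {
      stop("samples absent from population map: ",
           paste(missing, collapse = ", "))
    }
  }
  pm
}

#' Write a population map TSV
#' @param popmap data frame with `sample`, `population` columns
#' @param path output path
#' @export
write_population_map <- function(popmap, path) {
  utils::write.table(popmap, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene intervals from a BED file
#'
#' BED is 0-based half-open; the returned `GRanges` follows Bioconductor's
#' 1-based closed convention, so a BED interval \[0, 100) becomes
#' positions 1..100. Strand is taken from column 6 when present;
#' strand "*" is treated as "+" downstream.
#'
#' @param path BED path (3-6 columns)
#' @return a `GRanges` of gene intervals
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write gene intervals as BED6
#' @param genes a `GRanges`
#' @param path output path
#' @export
write_bed <- function(genes, path) {
  rtracklayer::export(genes, path, format = "BED")
  invisible(path)
}

#' Write a phylogenetic tree as Newick
#' @param tree an ape `phylo` object (node labels, when present, carry
#'   bootstrap support)
#' @param path output path
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file
#' @return an ape `phylo`
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Write a window statistics table as TSV
#' @param tab data frame of per-window statistics
#' @param path output path
#' @export
write_window_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a window statistics table written by [write_window_table()]
#' @param path TSV path
#' @return data frame
#' @export
read_window_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Classify SNP positions relative to gene intervals
#'
#' Assigns each locus one of `genic`, `upstream5kb`, `downstream5kb`,
#' `intergenic`, with priority genic > upstream > downstream. Upstream and
#' downstream are 5' and 3' of the gene respecting its strand; unstranded
#' genes are treated as plus-strand.
#'
#' @param loci locus data frame (`chrom`, `pos`)
#' @param annotation `GRanges` of genes, as from [read_bed()]
#' @param flank flank size in bp (default 5000)
#' @return `loci` with a filled `location_class` column
#' @export
classify_locus_location <- function(loci, annotation, flank = 5000) {
  if (nrow(loci) == 0) {
    loci$location_class <- character(0)
    return(loci)
  }
  strand <- as.character(GenomicRanges::strand(annotation))
  strand[strand == "*"] <- "+"
  GenomicRanges::strand(annotation) <- strand
  snp <- GenomicRanges::GRanges(loci$chrom,
                                IRanges::IRanges(loci$pos, loci$pos))
  up <- GenomicRanges::flank(annotation, flank, start = TRUE)
  down <- GenomicRanges::flank(annotation, flank, start = FALSE)
  cls <- rep("intergenic", nrow(loci))
  hit <- function(gr) {
    IRanges::overlapsAny(snp, gr, ignore.strand = TRUE)
  }
  cls[hit(down)] <- "downstream5kb"
  cls[hit(up)] <- "upstream5kb"
  cls[hit(annotation)] <- "genic"
  loci$location_class <- cls
  loci
}
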
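#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF 4.x file (via vcfR), keeping biallelic SNP records only.
#' Genotype codes count ALT alleles from the GT field regardless of the
#' phasing separator; missing GT becomes `NA`. Per-genotype DP is captured
#' when present, and the INFO MQ value (RMS mapping quality) is carried as
#' the per-site `qual` score when available, falling back to the QUAL
#' column.
#'
#' @param path path to an uncompressed or gzipped VCF
#' @return a [geno_matrix()]
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(geno_matrix(
      matrix(integer(0), nrow = max(0L, ncol(v@gt) - 1L), ncol = 0,
             dimnames = list(colnames(v@gt)[-1], NULL)),
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0))))
  }
  bad_alt <- which(is.na(fix$ALT) | grepl(",", fix$ALT) |
                     nchar(fix$REF) != 1 | nchar(fix$ALT) != 1)
  if (length(bad_alt)) {
    stop("non-SNP or multiallelic ALT at record(s) ",
         paste(utils::head(bad_alt, 5), collapse = ", "),
         " (", fix$CHROM[bad_alt[1]], ":", fix$POS[bad_alt[1]], ")")
  }
  key <- paste(fix$CHROM, fix$POS)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))
    stop("duplicate position at record(s) ",
         paste(utils::head(d, 5), collapse = ", "),
         " (", key[d[1]], ")")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(x) {
    # "0/1", "1|1", ".", "./." -> ALT-allele dosage
    a <- strsplit(x, "[/|]")
    vapply(a, function(al) {
      if (length(al) == 0 || anyNA(al) || any(al == "." | al == "")) {
        return(NA_integer_)
      }
      al <- suppressWarnings(as.integer(al))
      if (anyNA(al) || any(al > 1)) return(NA_integer_)
      sum(al)
    }, integer(1))
  }
  G <- t(apply(gt, 1, alt_count))
  if (nrow(gt) == 1) G <- matrix(G, nrow = 1)
  G <- t(G)  # samples x loci
  rownames(G) <- colnames(gt)
  D <- NULL
  if ("DP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    D <- t(dp)
    storage.mode(D) <- "integer"
  }
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "MQ")))
  qual <- if (all(is.na(mq))) suppressWarnings(as.numeric(fix$QUAL)) else mq
  loci <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, qual = qual,
                     stringsAsFactors = FALSE)
  o <- order(loci$chrom, loci$pos)
  geno_matrix(G[, o, drop = FALSE], loci[o, , drop = FALSE],
              D = if (!is.null(D)) D[, o, drop = FALSE])
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits GT (unphased) and, when the matrix carries depths, DP per
#' genotype; the per-site `qual` score is written as INFO MQ. The output
#' round-trips through [read_vcf()] with identical GT and DP.
#'
#' @param gm a [geno_matrix()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=herdscan",
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'),
    con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", gm$samples),
                   collapse = "\t"), con)
  has_dp <- !is.null(gm$D)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$G + 1L], nrow = nrow(gm$G))
  gt_str[is.na(gm$G)] <- "./."
  if (has_dp) {
    dp <- gm$D
    dp_str <- matrix(as.character(dp), nrow = nrow(dp))
    dp_str[is.na(dp)] <- "."
    gt_str <- matrix(paste(gt_str, dp_str, sep = ":"), nrow = nrow(gt_str))
  }
  info <- ifelse(is.na(gm$loci$qual), ".",
                 paste0("MQ=", format(gm$loci$qual, trim = TRUE)))
  lines <- vapply(seq_len(nrow(gm$loci)), function(l) {
    paste(c(gm$loci$chrom[l], gm$loci$pos[l], ".", gm$loci$ref[l],
            gm$loci$alt[l], ".", "PASS", info[l],
            if (has_dp) "GT:DP" else "GT", gt_str[, l]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}
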
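#' Genomic relationship matrix
#'
#' VanRaden/GCTA-style GRM: G_ij = (1/m_ij) * sum_l
#' (g_il - 2 p_l)(g_jl - 2 p_l) / (2 p_l (1 - p_l)), with p_l the
#' in-sample ALT frequency. Missing genotypes contribute 0 to the sum
#' and reduce that pair's locus count m_ij. Monomorphic loci must be
#' filtered out upstream.
#'
#' @param gm a MAF-filtered [geno_matrix()]
#' @return n x n symmetric relationship matrix
#' @export
grm <- function(gm) {
  p <- allele_frequency(gm)
  if (any(!is.na(p) & (p <= 0 | p >= 1))) {
    stop("monomorphic loci present; apply a MAF filter first")
  }
  W <- sweep(gm$G, 2, 2 * p, "-") / rep(sqrt(2 * p * (1 - p)),
                                        each = nrow(gm$G))
  called <- !is.na(W)
  W[!called] <- 0
  M <- tcrossprod(called * 1)        # shared called loci per pair
  if (any(M == 0)) stop("sample pair with no shared called loci")
  K <- tcrossprod(W) / M
  dimnames(K) <- list(gm$samples, gm$samples)
  K
}

#' Principal components from a relationship matrix
#'
#' Eigendecomposition of the (symmetric) GRM; coordinates are
#' eigenvectors scaled by the square root of their (non-negative)
#' eigenvalues, ordered by descending eigenvalue, with the sign fixed so
#' each axis's first nonzero loading is positive. Variance proportions
#' are eigenvalues over the sum of positive eigenvalues.
#'
#' @param K symmetric relationship matrix
#' @param n_components number of axes to return
#' @return list with `coords` (n x k), `varprop` (length k), `values`
#'   (all eigenvalues)
#' @export
pca_grm <- function(K, n_components = 3) {
  if (any(!is.finite(K))) stop("relationship matrix has non-finite entries")
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  k <- min(n_components, ncol(K))
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    nz <- which(abs(vec[, j]) > 1e-12)[1]
    if (!is.na(nz) && vec[nz, j] < 0) vec[, j] <- -vec[, j]
  }
  lam <- pmax(e$values[seq_len(k)], 0)
  coords <- sweep(vec, 2, sqrt(lam), "*")
  rownames(coords) <- rownames(K)
  colnames(coords) <- paste0("PC", seq_len(k))
  pos <- sum(e$values[e$values > 0])
  list(coords = coords, varprop = e$values[seq_len(k)] / pos,
       values = e$values)
}
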
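#' Pairwise p-distance between samples
#'
#' d(i,j) = sum over shared called loci of |g_i - g_j| / (2 * m_ij),
#' with m_ij the number of loci called in both samples (pairwise
#' deletion). Ranges from 0 (identical genotypes) to 1 (opposite
#' homozygotes everywhere).
#'
#' @param gm a [geno_matrix()] with at least 2 samples
#' @return symmetric `dist`-compatible matrix with zero diagonal
#' @export
p_distance <- function(gm) {
  n <- length(gm$samples)
  if (n < 2) stop("p-distance needs at least 2 samples")
  G <- gm$G
  d <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  for (i in seq_len(n - 1)) {
    gi <- G[i, ]
    for (j in (i + 1):n) {
      gj <- G[j, ]
      ok <- !is.na(gi) & !is.na(gj)
      m_ij <- sum(ok)
      if (m_ij == 0) {
        stop("samples ", gm$samples[i], " and ", gm$samples[j],
             " share no called loci")
      }
      d[i, j] <- d[j, i] <- sum(abs(gi[ok] - gj[ok])) / (2 * m_ij)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via ape's NJ) with negative branch lengths
#' clamped to zero. An additive distance matrix is recovered exactly
#' (topology and branch lengths).
#'
#' @param dm symmetric distance matrix with sample names
#' @return an unrooted ape `phylo`
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (any(!is.finite(dm))) stop("distance matrix has non-finite entries")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix is not symmetric")
  if (nrow(dm) < 3) stop("neighbor joining needs at least 3 taxa")
  tree <- ape::nj(dm)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Bootstrap support for the NJ tree
#'
#' Resamples loci with replacement, recomputes the p-distance and NJ
#' tree for each replicate, and attaches to each internal edge of the
#' full-data tree the fraction of replicates containing that
#' bipartition (as node labels in [0,1]).
#'
#' @param gm a [geno_matrix()]
#' @param n_reps number of bootstrap replicates
#' @param seed optional seed
#' @return list with `tree` (node labels = support) and `support`
#'   (numeric vector per internal node)
#' @export
bootstrap_support <- function(gm, n_reps = 100, seed = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ref <- neighbor_joining(p_distance(gm))
  m <- ncol(gm$G)
  boots <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(m, m, replace = TRUE)
    bgm <- gm
    bgm$G <- gm$G[, idx, drop = FALSE]
    # locus table irrelevant for distances; keep dims consistent
    boots[[r]] <- neighbor_joining(p_distance(bgm))
  }
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- counts / n_reps
  ref$node.label <- formatC(support, format = "g")
  list(tree = ref, support = support)
}

#' Root a tree on the edge leading to an outgroup
#'
#' @param tree an ape `phylo`
#' @param outgroup_label tip label of the outgroup
#' @return rooted `phylo`
#' @export
root_with_outgroup <- function(tree, outgroup_label) {
  if (!outgroup_label %in% tree$tip.label) {
    stop("outgroup '", outgroup_label, "' is not a tip of the tree")
  }
  ape::root(tree, outgroup = outgroup_label, resolve.root = TRUE)
}
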
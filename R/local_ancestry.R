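#' Diploid local-ancestry inference by HMM
#'
#' Genotype-based forward-backward smoothing over the three unordered
#' diploid ancestry states \{(1,1), (1,2), (2,2)\}. Emissions come from
#' the reference panels' allele frequencies (each haploid allele
#' Bernoulli(f_k), genotype = sum of two independent haplotype draws);
#' panel frequencies of exactly 0 or 1 are clamped to
#' \[eps, 1-eps\] with eps = 1/(2 n_panel + 1). Along each chromosome the
#' two haplotypes switch ancestry independently with probability
#' 1 - exp(-d G) per inter-locus genetic distance d (re-drawing from the
#' stationary law (q, 1-q)), composed into diploid transitions. Missing
#' genotypes emit uninformatively. With `prior = NULL` a two-pass scheme
#' is used: a flat first pass, then per-individual q re-estimated from
#' the first-pass posterior dosages.
#'
#' @param gm_query query cohort [geno_matrix()]
#' @param panel1,panel2 reference panels for ancestries 1 and 2 (same
#'   loci as the query)
#' @param gen_since_admix generations G setting the tract scale
#' @param recomb_rate Morgans per bp
#' @param prior per-haplotype prior probability of ancestry 1 (scalar or
#'   per-individual vector); `NULL` for the two-pass default
#' @param viterbi also compute joint-MAP (Viterbi) state paths
#' @return list: `samples`; `posterior` (n x m x 3 array over states
#'   11/12/22); `dosage` (n x m expected ancestry-1 dosage);
#'   `hard_call` (n x m argmax dosage in \{0,1,2\}); `q_hat`
#'   (per-individual global ancestry-1 proportion = mean dosage / 2);
#'   `viterbi` (optional n x m dosage path)
#' @export
local_ancestry <- function(gm_query, panel1, panel2,
                           gen_since_admix = 10, recomb_rate = 1e-8,
                           prior = NULL, viterbi = FALSE) {
  loci <- gm_query$loci
  if (!identical(paste(panel1$loci$chrom, panel1$loci$pos),
                 paste(loci$chrom, loci$pos)) ||
      !identical(paste(panel2$loci$chrom, panel2$loci$pos),
                 paste(loci$chrom, loci$pos))) {
    stop("panels and query must share the same loci")
  }
  clamp_panel_freq <- function(panel) {
    f <- allele_frequency(panel)
    eps <- 1 / (2 * length(panel$samples) + 1)
    n_clamped <- sum(f <= 0 | f >= 1, na.rm = TRUE)
    if (n_clamped > 0) {
      message(n_clamped, " panel frequencies clamped to [",
              signif(eps, 3), ", ", signif(1 - eps, 3), "]")
    }
    pmin(pmax(f, eps), 1 - eps)
  }
  f1 <- clamp_panel_freq(panel1)
  f2 <- clamp_panel_freq(panel2)
  m <- nrow(loci)
  if (m < 2) stop("local ancestry needs at least 2 loci")
  n <- length(gm_query$samples)
  # emission matrix per state for each genotype value, 3 x m each
  emis_for <- function(fa, fb) {
    rbind(g0 = (1 - fa) * (1 - fb),
          g1 = fa * (1 - fb) + (1 - fa) * fb,
          g2 = fa * fb)
  }
  E <- list(s11 = emis_for(f1, f1), s12 = emis_for(f1, f2),
            s22 = emis_for(f2, f2))
  d <- c(0, diff(loci$pos)) * recomb_rate
  new_chrom <- c(TRUE, loci$chrom[-1] != loci$chrom[-m])
  s <- 1 - exp(-d * gen_since_admix)
  s[new_chrom] <- 1

  run_pass <- function(qv, want_viterbi) {
    post <- array(NA_real_, c(n, m, 3),
                  dimnames = list(gm_query$samples, NULL,
                                  c("s11", "s12", "s22")))
    vit <- if (want_viterbi) matrix(NA_integer_, n, m) else NULL
    for (i in seq_len(n)) {
      q <- qv[i]
      pi_h <- c(q, 1 - q)
      g <- gm_query$G[i, ]
      # per-locus emission over ordered states (11,12,21,22)
      e <- matrix(1, 4, m)
      ok <- !is.na(g)
      gi <- g[ok] + 1L
      e[1, ok] <- E$s11[cbind(gi, which(ok))]
      e[2, ok] <- E$s12[cbind(gi, which(ok))]
      e[3, ok] <- e[2, ok]
      e[4, ok] <- E$s22[cbind(gi, which(ok))]
      init <- as.vector(pi_h %o% pi_h)  # (11,21,12,22) order-safe: symmetric
      alpha <- matrix(0, 4, m)
      scal <- numeric(m)
      a <- init * e[, 1]
      scal[1] <- sum(a)
      alpha[, 1] <- a / scal[1]
      Tlist <- vector("list", m)
      for (t in 2:m) {
        Th <- (1 - s[t]) * diag(2) + s[t] * rbind(pi_h, pi_h)
        T4 <- Th %x% Th
        Tlist[[t]] <- T4
        a <- as.vector(crossprod(T4, alpha[, t - 1])) * e[, t]
        scal[t] <- sum(a)
        alpha[, t] <- a / scal[t]
      }
      beta <- matrix(0, 4, m)
      beta[, m] <- 1
      for (t in (m - 1):1) {
        b <- Tlist[[t + 1]] %*% (e[, t + 1] * beta[, t + 1])
        beta[, t] <- b / sum(b)
      }
      g4 <- alpha * beta
      g4 <- sweep(g4, 2, colSums(g4), "/")
      post[i, , 1] <- g4[1, ]
      post[i, , 2] <- g4[2, ] + g4[3, ]
      post[i, , 3] <- g4[4, ]
      if (want_viterbi) {
        lv <- matrix(-Inf, 4, m)
        bp <- matrix(0L, 4, m)
        lv[, 1] <- log(init) + log(e[, 1])
        for (t in 2:m) {
          lt <- log(Tlist[[t]])
          for (y in 1:4) {
            cand <- lv[, t - 1] + lt[, y]
            bp[y, t] <- which.max(cand)
            lv[y, t] <- cand[bp[y, t]] + log(e[y, t])
          }
        }
        path <- integer(m)
        path[m] <- which.max(lv[, m])
        for (t in (m - 1):1) path[t] <- bp[path[t + 1], t + 1]
        vit[i, ] <- c(2L, 1L, 1L, 0L)[path]  # ancestry-1 dosage
      }
    }
    list(post = post, vit = vit)
  }

  if (is.null(prior)) {
    first <- run_pass(rep(0.5, n), FALSE)
    dos1 <- first$post[, , 1] * 2 + first$post[, , 2]
    qv <- pmin(pmax(rowMeans(matrix(dos1, n)) / 2, 0.01), 0.99)
  } else {
    qv <- rep_len(prior, n)
  }
  res <- run_pass(qv, viterbi)
  dosage <- matrix(res$post[, , 1] * 2 + res$post[, , 2], n)
  hard <- matrix(c(2L, 1L, 0L)[apply(res$post, c(1, 2), which.max)], n)
  out <- list(samples = gm_query$samples, posterior = res$post,
              dosage = dosage, hard_call = hard,
              q_hat = rowMeans(dosage) / 2)
  if (viterbi) out$viterbi <- res$vit
  out
}

#' Population-level global ancestry proportions
#'
#' Per-individual global proportion of ancestry 1 is the mean posterior
#' dosage / 2 over loci; the population value is the mean over its
#' individuals. The two ancestry proportions sum to 1.
#'
#' @param post a [local_ancestry()] result
#' @param popmap data frame (`sample`, `population`)
#' @return data frame: `population`, `prop_anc1`, `prop_anc2`
#' @export
global_ancestry_summary <- function(post, popmap) {
  pm <- popmap[match(post$samples, popmap$sample), ]
  pops <- unique(pm$population)
  out <- lapply(pops, function(p) {
    q <- post$q_hat[pm$population == p]
    data.frame(population = p, n = length(q),
               prop_anc1 = mean(q), prop_anc2 = 1 - mean(q),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
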
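# Binomial admixture log-likelihood (constant binomial coefficients
# omitted): sum over called entries of g log d + (2-g) log(1-d),
# d = Q F.
admix_loglik <- function(G, Q, F_) {
  D <- Q %*% F_
  ll <- G * log(D) + (2 - G) * log(1 - D)
  sum(ll, na.rm = TRUE)
}

#' Fit an admixture model by EM
#'
#' Maximum-likelihood estimation of the classic admixture model:
#' genotype g_il ~ Binomial(2, d_il) with d_il = sum_k q_ik f_kl, where
#' Q (n x K) holds per-individual ancestry fractions on the simplex and
#' F (K x m) per-ancestry allele frequencies. Plain EM updates with
#' random restarts; the log-likelihood is non-decreasing at every
#' iteration and the best restart is kept. Missing genotypes are simply
#' dropped from the likelihood.
#'
#' @param gm a MAF-filtered [geno_matrix()]
#' @param K number of ancestral components (>= 1)
#' @param seed optional seed for the restarts
#' @param max_iter EM iteration cap per restart
#' @param tol stop when the log-likelihood gain drops below `tol`
#' @param n_restarts random restarts (best kept)
#' @return list with `Q`, `F` (row/col named), `loglik` (trace of the
#'   best restart), `K`, `converged`
#' @export
admixture_fit <- function(gm, K, seed = NULL, max_iter = 200,
                          tol = 1e-4, n_restarts = 3) {
  n <- length(gm$samples)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of samples")
  if (!is.null(seed)) set.seed(seed)
  G <- gm$G
  storage.mode(G) <- "double"
  called <- !is.na(G)
  m_i <- rowSums(called)
  if (any(m_i == 0)) stop("sample with no called genotypes")
  eps <- 1e-6
  p_obs <- allele_frequency(gm)
  if (K == 1) {
    Q <- matrix(1, n, 1, dimnames = list(gm$samples, "anc1"))
    F_ <- matrix(pmin(pmax(p_obs, eps), 1 - eps), 1,
                 dimnames = list("anc1", colnames(gm$G)))
    return(list(Q = Q, F = F_, loglik = admix_loglik(G, Q, F_), K = 1L,
                converged = TRUE))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    Q <- matrix(stats::rgamma(n * K, 1), n, K)
    Q <- Q / rowSums(Q)
    F_ <- matrix(pmin(pmax(
      rep(p_obs, each = K) + stats::rnorm(K * length(p_obs), 0, 0.05),
      eps), 1 - eps), K)
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      D <- Q %*% F_
      num_a <- G / D          # NA where missing
      num_b <- (2 - G) / (1 - D)
      EA <- matrix(0, K, ncol(G))  # expected ALT alleles from k per locus
      ET <- matrix(0, K, ncol(G))  # expected total alleles from k
      Qnew <- matrix(0, n, K)
      for (k in seq_len(K)) {
        Ak <- (Q[, k] %o% F_[k, ]) * num_a
        Bk <- (Q[, k] %o% (1 - F_[k, ])) * num_b
        Ak[!called] <- 0
        Bk[!called] <- 0
        EA[k, ] <- colSums(Ak)
        ET[k, ] <- EA[k, ] + colSums(Bk)
        Qnew[, k] <- rowSums(Ak + Bk) / (2 * m_i)
      }
      Q <- Qnew / rowSums(Qnew)
      F_ <- pmin(pmax(EA / pmax(ET, .Machine$double.xmin), eps), 1 - eps)
      ll <- admix_loglik(G, Q, F_)
      trace <- c(trace, ll)
      if (is.finite(ll_old) && ll - ll_old < tol) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    if (is.null(best) || trace[length(trace)] > best$loglik[length(best$loglik)]) {
      best <- list(Q = Q, F = F_, loglik = trace, K = as.integer(K),
                   converged = converged)
    }
  }
  dimnames(best$Q) <- list(gm$samples, paste0("anc", seq_len(K)))
  dimnames(best$F) <- list(paste0("anc", seq_len(K)), colnames(gm$G))
  best
}

#' Cross-validated choice of the number of ancestries K
#'
#' Masks a random 1/folds of the called genotype entries per fold, fits
#' the admixture model on the unmasked entries, and scores the masked
#' ones by mean squared dosage error ((g - 2 d)/2)^2 with d the fitted
#' allele dose. A fold whose mask would empty a locus is re-drawn
#' (bounded retries). Reports the per-K error averaged over folds and
#' the minimizing K.
#'
#' @param gm a MAF-filtered [geno_matrix()]
#' @param K_range integer vector of K values to score
#' @param folds number of folds (>= 2)
#' @param seed optional seed
#' @param ... passed to [admixture_fit()]
#' @return list with `cv` (data frame `K`, `cv_error`) and `best_K`
#' @export
admixture_cv <- function(gm, K_range = 1:3, folds = 5, seed = NULL,
                         ...) {
  if (folds < 2) stop("folds must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  called_idx <- which(!is.na(gm$G))
  n_loci <- ncol(gm$G)
  for (try in 1:10) {
    fold_of <- sample(rep_len(seq_len(folds), length(called_idx)))
    ok <- TRUE
    for (f in seq_len(folds)) {
      masked <- called_idx[fold_of == f]
      left <- tabulate(((called_idx[fold_of != f] - 1) %/% nrow(gm$G)) + 1,
                       n_loci)
      if (any(left == 0)) { ok <- FALSE; break }
    }
    if (ok) break
    if (try == 10) stop("could not draw a CV mask keeping all loci covered")
  }
  errs <- matrix(NA_real_, length(K_range), folds)
  for (f in seq_len(folds)) {
    masked <- called_idx[fold_of == f]
    gtrain <- gm
    gtrain$G[masked] <- NA_integer_
    for (ki in seq_along(K_range)) {
      fit <- admixture_fit(gtrain, K_range[ki], ...)
      Dh <- fit$Q %*% fit$F
      errs[ki, f] <- mean(((gm$G[masked] - 2 * Dh[masked]) / 2)^2)
    }
  }
  cv <- data.frame(K = K_range, cv_error = rowMeans(errs))
  list(cv = cv, best_K = K_range[which.min(cv$cv_error)])
}

#' Align fitted ancestry components to reference frequencies
#'
#' Resolves label switching by greedily matching rows of the fitted F to
#' reference frequency vectors by smallest mean absolute difference.
#'
#' @param fit an [admixture_fit()] result
#' @param f_ref K x m matrix of reference per-ancestry frequencies
#' @return `fit` with rows of `F` and columns of `Q` permuted to match
#'   `f_ref` row order
#' @export
align_ancestries <- function(fit, f_ref) {
  K <- fit$K
  stopifnot(nrow(f_ref) == K)
  cost <- matrix(0, K, K)
  for (a in seq_len(K)) for (b in seq_len(K)) {
    cost[a, b] <- mean(abs(f_ref[a, ] - fit$F[b, ]))
  }
  perm <- integer(K)
  avail <- seq_len(K)
  for (a in seq_len(K)) {
    b <- avail[which.min(cost[a, avail])]
    perm[a] <- b
    avail <- setdiff(avail, b)
  }
  fit$F <- fit$F[perm, , drop = FALSE]
  fit$Q <- fit$Q[, perm, drop = FALSE]
  fit
}
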
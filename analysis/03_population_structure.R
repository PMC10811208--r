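#!/usr/bin/env Rscript
# Stage 3 — population structure: NJ tree with bootstrap and outgroup
# rooting, GRM + PCA, and admixture with cross-validated K.
#
# The outgroup is a synthetic distant taxon drawn far from both
# ancestries, standing in for an outgroup species.

suppressMessages(library(herdscan))

out <- "results"
gm <- read_vcf(file.path(out, "merged_filtered.vcf"))
popmap <- read_population_map(file.path(out, "sim", "popmap.tsv"))

# subsample for the individual tree so the bootstrap stays light
set.seed(1)
keep <- unlist(lapply(split(popmap$sample, popmap$population),
                      function(s) head(intersect(s, gm$samples), 8)))
gm_tree <- gm_subset(gm, samples = keep)
# synthetic outgroup: homozygous for rare/common alleles far from both
p <- allele_frequency(gm_tree)
og <- geno_matrix(matrix(as.integer(p < 0.5) * 2L, 1,
                         dimnames = list("OUTGROUP", NULL)),
                  gm_tree$loci)
gm_tree <- merge_datasets(gm_tree, og)
bs <- bootstrap_support(gm_tree, n_reps = 100, seed = 2)
tree <- root_with_outgroup(bs$tree, "OUTGROUP")
write_newick(tree, file.path(out, "nj_tree.nwk"))
cat("NJ tree over", length(keep), "samples + outgroup;",
    "mean bootstrap support", sprintf("%.2f", mean(bs$support)), "\n")

# GRM + PCA over all samples
K <- grm(gm)
pc <- pca_grm(K, 3)
cat("PCA variance proportions:",
    sprintf("%.1f%%", 100 * pc$varprop), "\n")
coords <- data.frame(sample = rownames(pc$coords), pc$coords,
                     population = popmap$population[
                       match(rownames(pc$coords), popmap$sample)])
write_window_table(coords, file.path(out, "pca_coords.tsv"))

# admixture, K = 1..4 with 3-fold CV
cv <- admixture_cv(gm, K_range = 1:4, folds = 3, seed = 3,
                   n_restarts = 1, max_iter = 100)
print(cv$cv)
cat("Cross-validation favours K =", cv$best_K, "\n")
fit <- admixture_fit(gm, cv$best_K, seed = 4)
qtab <- data.frame(sample = rownames(fit$Q), fit$Q,
                   population = popmap$population[
                     match(rownames(fit$Q), popmap$sample)])
write_window_table(qtab, file.path(out, "admixture_Q.tsv"))
cat("Q matrix written to results/admixture_Q.tsv\n")
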
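#!/usr/bin/env Rscript
# Stage 4 — local-ancestry inference for the crossbred cohorts against
# the two ancestral panels, and the resulting global lineage
# proportions; compared against the simulator's ground truth.

suppressMessages(library(herdscan))

out <- "results"
gm <- read_vcf(file.path(out, "merged_filtered.vcf"))
popmap <- read_population_map(file.path(out, "sim", "popmap.tsv"))
truth <- utils::read.table(file.path(out, "sim", "xbg_truth.tsv"),
                           header = TRUE, sep = "\t")

p1 <- gm_subset(gm, samples = popmap$sample[popmap$population == "BS"])
p2 <- gm_subset(gm, samples = popmap$sample[popmap$population == "KZ"])
props <- list()
for (cohort in c("XBG", "XBH")) {
  q <- gm_subset(gm, samples = intersect(
    popmap$sample[popmap$population == cohort], gm$samples))
  la <- local_ancestry(q, p1, p2, gen_since_admix = 10)
  gs <- global_ancestry_summary(la, popmap)
  props[[cohort]] <- gs
  cat(sprintf("%s: %.2f%% BS / %.2f%% KZ lineage\n", cohort,
              100 * gs$prop_anc1, 100 * gs$prop_anc2))
  if (cohort == "XBG") {
    # truth comparison at the loci retained after filtering
    key <- paste(gm$loci$chrom, gm$loci$pos)
    tkey <- paste(truth$chrom, truth$pos)
    tw <- truth[tkey %in% key & truth$sample %in% la$samples, ]
    q_true <- tapply(tw$dosage / 2, tw$sample, mean)[la$samples]
    cat(sprintf("  mean |q_hat - q_true| = %.4f\n",
                mean(abs(la$q_hat - q_true))))
  }
  write_window_table(
    data.frame(sample = la$samples, q_bs = la$q_hat,
               q_kz = 1 - la$q_hat),
    file.path(out, paste0("ancestry_", tolower(cohort), ".tsv")))
}
res <- do.call(rbind, props)
write_window_table(res, file.path(out, "global_ancestry.tsv"))
cat("Global proportions written to results/global_ancestry.tsv\n")
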
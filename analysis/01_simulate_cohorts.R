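#!/usr/bin/env Rscript
# Stage 1 — build the synthetic study system.
#
# Two diverged ancestral panels (BS, KZ; Balding-Nichols F = 0.2), a
# crossbred cohort (XBG) with Beta-distributed individual ancestry
# around a 37.22% BS / 62.78% KZ mean, a near-pure cohort (XBH, 95.14%
# BS), one implanted selective sweep, platform effects (SLAF-like 25%
# missingness for XBG, WGS-like 2% for the rest) on partially
# overlapping marker sets, and a tiled gene annotation. Everything is
# written as plain text (VCF / TSV / BED) under results/sim/.

suppressMessages(library(herdscan))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20260923)
study <- simulate_study(cfg)

write_vcf(study$gm_slaf, file.path(out, "xbg_slaf.vcf"))
write_vcf(study$gm_wgs, file.path(out, "panels_xbh_wgs.vcf"))
write_population_map(study$popmap, file.path(out, "popmap.tsv"))
write_bed(study$annotation, file.path(out, "genes.bed"))
write_truth_tsv(study$truth$XBG, study$loci,
                file.path(out, "xbg_truth.tsv"))

cat("Simulated", nrow(study$loci), "loci on",
    length(cfg$chrom_lengths), "chromosomes\n")
cat("Cohorts:", paste(sprintf("%s=%d", names(table(study$popmap$population)),
                              table(study$popmap$population)),
                      collapse = ", "), "\n")
cat("True mean BS-ancestry: XBG",
    sprintf("%.4f", mean(study$truth$XBG$q_true)), "| XBH",
    sprintf("%.4f", mean(study$truth$XBH$q_true)), "\n")
cat("Sweep implanted at", cfg$sweep_regions[[1]]$chrom, ":",
    cfg$sweep_regions[[1]]$start, "-", cfg$sweep_regions[[1]]$end,
    "in", cfg$sweep_regions[[1]]$target, "\n")
cat("Wrote VCF/popmap/BED/truth under", out, "\n")
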
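#!/usr/bin/env Rscript
# Stage 2 — merge the two platform call sets, apply the standard locus
# filters (depth >= 4, missingness <= 0.3, site quality >= 20,
# MAF >= 0.01), and summarize per-population diversity (Ho, He, Nei,
# PIC, MAF).

suppressMessages(library(herdscan))

out <- "results"
sim <- "results/sim"
gm_slaf <- read_vcf(file.path(sim, "xbg_slaf.vcf"))
gm_wgs <- read_vcf(file.path(sim, "panels_xbh_wgs.vcf"))
popmap <- read_population_map(file.path(sim, "popmap.tsv"))

merged <- merge_datasets(gm_slaf, gm_wgs)
cat("Platform marker sets:", ncol(gm_slaf$G), "SLAF,", ncol(gm_wgs$G),
    "WGS;", ncol(merged$G), "shared loci after merging\n")

filt <- filter_loci(merged, min_depth = 4, max_missing = 0.3,
                    min_maf = 0.01, min_site_quality = 20)
print(filt$report)
write_window_table(filt$report, file.path(out, "filter_report.tsv"))
write_vcf(filt$gm, file.path(out, "merged_filtered.vcf"))

div <- population_summary(filt$gm, popmap)
print(div, digits = 4)
write_window_table(div, file.path(out, "diversity_summary.tsv"))
cat("Diversity summary written to results/diversity_summary.tsv\n")
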
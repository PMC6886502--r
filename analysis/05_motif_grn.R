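#!/usr/bin/env Rscript

# Stage 5: promoter extraction, PWM threshold calibration and scanning,
# motif enrichment of the CZ gene set, and GRN edge-table construction.

library(apexatlas)

atlas <- read_atlas("scratch/atlas")
nr <- normalize_rpm(atlas$counts, atlas$design)
expressed <- filter_expressed(nr$profiles)

prom <- extract_promoters(atlas$gene_models, atlas$genome,
                          up = 1000, down = 500)
prom <- prom[prom$gene %in% expressed, ]
cat(sprintf("%d promoters extracted (-1000/+500 around the TSS)\n",
            nrow(prom)))

scan <- scan_promoter_set(atlas$pwms, prom, p_value = 1e-4)
for (p in scan$pwms)
  cat(sprintf("  %s: threshold %.2f bits (match p = %.2g)\n",
              p$id, p$threshold, p$match_p))

# foreground: the recovered CZ-archetype cluster genes
clusters <- read.delim("results/clusters.tsv")
fg <- intersect(clusters$gene[clusters$archetype == "CZ"], prom$gene)
cat(sprintf("CZ foreground: %d genes\n", length(fg)))
enr <- motif_enrichment(scan, fg, prom$gene)
print(enr$per_pwm, row.names = FALSE)
write.table(enr$per_pwm, "results/motif_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

fc <- read.delim("results/family_pc_corr.tsv")
fc1 <- fc[fc$pc == "PC1", ]
grn <- build_grn(scan, family_sign = setNames(fc1$sign, fc1$family),
                 cz_genes = fg)
write.table(grn$edges, "results/grn_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("GRN: %d edges; mean distinct matched families per CZ gene: %.2f\n",
            nrow(grn$edges), mean(grn$family_counts$n_families)))
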
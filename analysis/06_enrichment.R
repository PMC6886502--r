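#!/usr/bin/env Rscript

# Stage 6: divergence-from-expectation enrichment analyses — entropy
# binned target enrichment, per-domain class enrichment, and
# trait-associated SNP proximity enrichment.

library(apexatlas)

atlas <- read_atlas("scratch/atlas")
nr <- normalize_rpm(atlas$counts, atlas$design)
expressed <- filter_expressed(nr$profiles)
se <- classify_specific(nr$profiles, expressed)
H <- setNames(se$H, se$gene)

targets <- intersect(atlas$target_sets$planted_targets, expressed)
binned <- binned_target_enrichment(H, targets, n_bins = 20)
write.table(binned, "results/binned_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
lo <- binned[binned$bin <= 10 & !is.na(binned$p), ]
cat(sprintf("binding targets vs entropy score: %d/%d low-score bins enriched (p < 0.05, D > 0)\n",
            sum(lo$p < 0.05 & lo$divergence > 0), nrow(lo)))

cls <- class_target_enrichment(split(se$gene, se$assigned_domain),
                               targets)
write.table(cls, "results/class_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

dyn <- intersect(select_dynamic_genes(nr$profiles[expressed, ]),
                 expressed)
near <- genes_near_snps(atlas$gene_models, atlas$snp_table,
                        window = 10000)
tas <- tas_proximity_enrichment(dyn, expressed, near$by_category)
write.table(tas, "results/tas_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("dynamic genes vs trait-associated SNP proximity:\n")
print(tas, row.names = FALSE)
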
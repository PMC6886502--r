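#!/usr/bin/env Rscript

# Stage 4: PCA of the standardized TF expression matrix, TF-family to
# principal-component correlation, and cumulative signed TF profiles.

library(apexatlas)

atlas <- read_atlas("scratch/atlas")
nr <- normalize_rpm(atlas$counts, atlas$design)
expressed <- filter_expressed(nr$profiles)
tfg <- intersect(atlas$tf_annotation$gene, expressed)

pca <- tf_pca(nr$profiles, tfg, npcs = 3)
cat(sprintf("TF PCA on %d expressed TFs; variance explained: %s\n",
            length(tfg),
            paste(sprintf("%.1f%%", 100 * pca$variance_explained[1:3]),
                  collapse = ", ")))
write.table(data.frame(domain = rownames(pca$scores), pca$scores,
                       check.names = FALSE),
            "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

fc <- family_pc_correlation(pca, atlas$tf_annotation, threshold = 0.6)
write.table(fc, "results/family_pc_corr.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
pc1 <- fc[fc$pc == "PC1" & fc$correlated, ]
cat("families correlated with PC1 (|r| >= 0.6):\n")
print(pc1[order(-abs(pc1$r)), c("family", "r", "sign", "n_members")],
      row.names = FALSE)

cum <- cumulative_signed_expression(nr$profiles, atlas$tf_annotation,
                                    pc1$family[pc1$sign == "positive"],
                                    pc1$family[pc1$sign == "negative"])
write.table(data.frame(sign = rownames(cum), cum, check.names = FALSE),
            "results/cumulative_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("cumulative positive-set profile peaks in:",
    names(which.max(cum["positive", ])), "\n")
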
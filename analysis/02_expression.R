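#!/usr/bin/env Rscript

# Stage 2: normalization, expression filtering, correlation structure,
# entropy-based domain specificity, and Tip-vs-P0 differential
# expression on the reference atlas.

library(apexatlas)

atlas <- read_atlas("scratch/atlas")
nr <- normalize_rpm(atlas$counts, atlas$design)
expressed <- filter_expressed(nr$profiles, min_rpm = 2)
cat(sprintf("%d of %d genes expressed at >= 2 RPM in some domain\n",
            length(expressed), nrow(atlas$counts)))

corr <- pairwise_correlation(nr$profiles)
write.table(data.frame(domain = rownames(corr), corr,
                       check.names = FALSE),
            "results/correlation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

se <- classify_specific(nr$profiles, expressed, cutoff = 2.33)
fit <- calibrate_se_cutoff(se$H)
cat(sprintf("entropy scores: chi-square moment fit df = %.2f (GOF p = %.3g)\n",
            fit$df, fit$gof_p))
cat(sprintf("%d domain-specific genes (SE < 2.33); top domains:\n",
            sum(se$specific)))
print(sort(table(se$assigned_domain[se$specific]), decreasing = TRUE))
write.table(se, "results/se_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

de <- differential_expression(atlas$counts, atlas$design, "Tip", "P0",
                              alpha = 0.01)
de <- de[de$gene %in% expressed, ]
cat(sprintf("Tip vs P0: %d of %d expressed genes differential at q < 0.01\n",
            sum(de$significant), nrow(de)))
write.table(de, "results/de_Tip_vs_P0.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
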
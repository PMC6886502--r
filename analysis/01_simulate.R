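#!/usr/bin/env Rscript

# Stage 1: generate the reference synthetic shoot-apex atlas.
#
# Builds the full 5,000-gene atlas (counts over 10 domains x 2
# replicates, gene models, genome with planted promoter motifs, SNP
# table, planted target set) and writes it as plain-text interchange
# files under scratch/atlas/. Everything downstream reads from there.

library(apexatlas)

seed <- 20260929 %% 1000L            # fixed study seed
cfg <- sim_config(seed = seed)
atlas <- simulate_atlas(cfg)
dir <- "scratch/atlas"
write_atlas(atlas, dir)

cat("Synthetic atlas written to", dir, "\n")
cat(sprintf("  genes: %d  libraries: %d  planted specific: %d\n",
            nrow(atlas$counts), ncol(atlas$counts),
            sum(!is.na(atlas$truth$specific_domain))))
cat(sprintf("  planted archetype genes: %d  TFs: %d  SNPs: %d\n",
            sum(!is.na(atlas$truth$archetype)),
            nrow(atlas$tf_annotation), nrow(atlas$snp_table)))
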
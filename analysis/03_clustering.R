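#!/usr/bin/env Rscript

# Stage 3: dynamic-gene selection across the meristem->P3 ontogeny and
# CAST clustering into functional-domain archetypes.

library(apexatlas)

atlas <- read_atlas("scratch/atlas")
nr <- normalize_rpm(atlas$counts, atlas$design)
expressed <- filter_expressed(nr$profiles)
dyn <- select_dynamic_genes(nr$profiles[expressed, ], fold = 2,
                            floor_rpm = 1)
cat(sprintf("%d dynamically expressed genes (>= 2-fold, meristem..P3)\n",
            length(dyn)))

cast <- cast_cluster(nr$profiles[dyn, ontogeny_tissues()], t = 0.8)
arch <- cluster_archetypes(cast, nr$profiles, min_size = 5)
cat(sprintf("CAST: %d clusters at affinity 0.8; archetype labels:\n",
            length(cast$clusters)))
print(table(arch$archetype[arch$size >= 5]))

asg <- merge(cast$assignments, arch[, c("cluster", "archetype")],
             by = "cluster")[, c("gene", "cluster", "archetype")]
write.table(asg[order(asg$gene), ], "results/clusters.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(arch, "results/cluster_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# recovery of the planted archetype structure
tt <- atlas$truth[!is.na(atlas$truth$archetype), ]
m <- merge(tt, cast$assignments, by = "gene")
tab <- table(m$archetype, m$cluster)
for (a in rownames(tab)) {
  cl <- colnames(tab)[which.max(tab[a, ])]
  cat(sprintf("  planted %-9s -> cluster %s labelled %s\n", a, cl,
              arch$archetype[arch$cluster == cl]))
}
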
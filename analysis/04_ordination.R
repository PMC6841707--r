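#!/usr/bin/env Rscript
# Stage 4 — environmental PCA, heterogeneity, NMDS, ANOSIM, vector fitting.
#
# NIPALS principal components of the log-transformed chemistry table;
# environmental heterogeneity per floodplain as dispersion around the
# floodplain centroid in PC space; Bray-Curtis NMDS of the family table
# with ANOSIM tests at biome/floodplain/zone scales and environmental
# vectors fitted onto the configuration.

library(floodnet)

dat <- "results/data"
counts <- read_count_table(file.path(dat, "counts.tsv"))
h <- read_sample_hierarchy(file.path(dat, "metadata.tsv"))
env <- read_env_table(file.path(dat, "env.tsv"))

fam <- collapse_taxa(rarefy(filter_taxa(counts), depth = 10000, seed = 31), 2)
h <- pair_samples(fam, h)$hierarchy
logev <- log(as.matrix(env[match(h$sample_id, env$sample_id), -1]))

pca <- nipals_pca(logev, n_axes = 2)
cat(sprintf("PCA: axis 1 %.0f%%, axis 2 %.0f%% of environmental variance\n",
            100 * pca$explained[1], 100 * pca$explained[2]))
write.table(data.frame(sample_id = h$sample_id, pca$scores),
            "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

disp <- group_dispersion(pca, h$floodplain)
write.table(disp$summary, "results/env_heterogeneity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

bc <- bray_curtis(fam)
nm <- nmds(bc, k = 2, n_starts = 20, seed = 41)
cat(sprintf("NMDS stress: %.3f (%d starts)\n", nm$stress, nm$n_starts))
write.table(data.frame(sample_id = h$sample_id, nm$scores),
            "results/nmds_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (scale_ in c("biome", "floodplain", "zone")) {
  g <- h[[scale_]]
  if (length(unique(g)) < 2) next
  an <- anosim(bc, g, n_perm = 999, seed = 42)
  cat(sprintf("ANOSIM %-10s R = %.3f (p = %.3g)\n", scale_, an$R, an$p))
}

ef <- envfit_vectors(nm, logev, n_perm = 999, seed = 43)
write.table(ef, "results/envfit.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Strongest environmental vectors on the NMDS:\n")
print(head(ef[order(-ef$r2), c("variable", "r2", "p")], 4), row.names = FALSE)
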
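#!/usr/bin/env Rscript
# Compositional differences among exometabolomes: angular + z-score
# transform of exometabolite relative abundances, PCoA ordination, and
# PERMANOVA partitioning by treatment, diel period and their interaction.

suppressMessages(library(reefexo))

dir <- "results/simulated"
md <- read_sample_metadata(file.path(dir, "sample_metadata.tsv"))
ft <- read_feature_table(file.path(dir, "feature_table.tsv"), md, "long")
cls <- classify_features(ft, md)

common <- cls$labels$feature_id[!cls$labels$class %in%
                                  c("background", "transient")]
ftc <- subset_features(ft, features = common,
                       samples = md$sample_id[md$role == "experimental"])
ord <- exometabolome_ordination(ftc, md, cls, n_perm = 999, seed = 1)

cat("PERMANOVA on exometabolite composition:\n")
print(ord$permanova)
cat("\nPairwise treatment contrasts (BH-adjusted):\n")
print(ord$pairwise)

write_tsv(ord$permanova, "results/permanova.tsv")
write_tsv(ord$pairwise, "results/permanova_pairwise.tsv")
pts <- data.frame(sample_id = rownames(ord$pcoa$points), ord$pcoa$points[, 1:2])
names(pts)[2:3] <- c("PCo1", "PCo2")
write_tsv(pts, "results/pcoa_coordinates.tsv")
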
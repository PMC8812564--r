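#!/usr/bin/env Rscript
# Molecular-subnetwork level analysis: aggregation of member relative
# abundances, producer enrichment (Dunnett vs Control with BH FDR, twofold
# rule), focus-network selection (abundant / diverse / enriched), class
# congruency with treatment associations, and the standardized heatmap.

suppressMessages(library(reefexo))

dir <- "results/simulated"
md <- read_sample_metadata(file.path(dir, "sample_metadata.tsv"))
ft <- read_feature_table(file.path(dir, "feature_table.tsv"), md, "long")
ann <- read_annotations(file.path(dir, "annotations.tsv"),
                        feature_ids = rownames(ft$areas))

cls <- classify_features(ft, md)
common <- cls$labels$feature_id[!cls$labels$class %in%
                                  c("background", "transient")]
ftc <- subset_features(ft, features = common,
                       samples = md$sample_id[md$role == "experimental"])

nets <- aggregate_subnetworks(ftc, ann, cls, md)
enr <- test_subnetwork_enrichment(nets, md)
write_tsv(enr, "results/subnetwork_enrichment.tsv")
cat(sprintf("%d of %d subnetworks enriched in at least one producer cell\n",
            length(unique(enr$subnetwork_id[enr$enriched])),
            nrow(nets$info)))

focus <- select_focus_subnetworks(nets, enr, md)
write_tsv(nets$info[nets$info$subnetwork_id %in% focus, ],
          "results/focus_subnetworks.tsv")

congr <- subnetwork_class_congruency(cls, ann)
print(congr)
write_tsv(congr, "results/congruency.tsv")

if (length(focus)) {
  H <- heatmap_matrix(focus, nets, ftc, md)
  hm <- data.frame(feature_id = rownames(H),
                   subnetwork_id = attr(H, "subnetwork_id"), H,
                   check.names = FALSE)
  write_tsv(hm, "results/heatmap_matrix.tsv")
  cat(sprintf("heatmap: %d features in %d focus subnetworks\n",
              nrow(H), length(focus)))
}
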
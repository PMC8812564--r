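#!/usr/bin/env Rscript
# Energetics (carbon-weighted NOSC and Gibbs energy of carbon oxidation)
# and abundance-weighted elemental stoichiometry of each producer's
# exometabolome, the feature-standardized robustness variant, and the
# coupling of exometabolite N:C / P:C with bulk dissolved N and P.

suppressMessages(library(reefexo))

dir <- "results/simulated"
md <- read_sample_metadata(file.path(dir, "sample_metadata.tsv"))
ft <- read_feature_table(file.path(dir, "feature_table.tsv"), md, "long")
ann <- read_annotations(file.path(dir, "annotations.tsv"),
                        feature_ids = rownames(ft$areas))
bulk <- read_bulk_chemistry(file.path(dir, "bulk_chemistry.tsv"))

cls <- classify_features(ft, md)
qf <- formula_quality_filter(ann)
common <- cls$labels$feature_id[!cls$labels$class %in%
                                  c("background", "transient")]
ftc <- subset_features(ft, features = common,
                       samples = md$sample_id[md$role == "experimental"])

st <- exometabolome_stoichiometry(ftc, md, cls, qf, diel = "Day")
write_tsv(st, "results/sample_stoichiometry.tsv")
cat("Per-producer daytime exometabolome means:\n")
print(aggregate(cbind(nosc, gibbs, NC, PC, OC, HC) ~ treatment, st, mean))

stz <- exometabolome_stoichiometry(ftc, md, cls, qf, diel = "Day",
                                   weighting = "zscore")
cat("\nRank correlation of producer NOSC, area vs z-score weighting:",
    round(cor(tapply(st$nosc, st$treatment, mean),
              tapply(stz$nosc, stz$treatment, mean), method = "spearman"), 2),
    "\n")

fits <- regress_stoichiometry_vs_bulk(st, bulk)
cat(sprintf("\nN:C predicts TDN: R2 = %.2f (p = %.2g)\n", fits$N$r2,
            fits$N$p))
cat(sprintf("P:C predicts TDP: R2 = %.2f (p = %.2g)\n", fits$P$r2,
            fits$P$p))

van_k <- cbind(qf[c("feature_id", "C", "H", "N", "O", "P", "S")],
               HC = qf$H / qf$C, OC = qf$O / qf$C, nosc = nosc(qf))
write_tsv(van_k, "results/van_krevelen.tsv")
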
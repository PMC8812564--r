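#!/usr/bin/env Rscript
# Producer effects on bulk biogeochemistry (ANOVA with FDR across analytes,
# two-sided Dunnett vs Control) and the coupling of DOC with the summed
# peak areas of the exudate and ambient metabolite pools.

suppressMessages(library(reefexo))

dir <- "results/simulated"
md <- read_sample_metadata(file.path(dir, "sample_metadata.tsv"))
ft <- read_feature_table(file.path(dir, "feature_table.tsv"), md, "long")
bulk <- read_bulk_chemistry(file.path(dir, "bulk_chemistry.tsv"))
cls <- classify_features(ft, md)

analytes <- c("DO", "pH", "DOC", "PO4", "NO3NO2", "NH4", "silicate",
              "TDN", "TDP", "DON", "DOP")
eff <- producer_effect_tests(bulk, md, analytes)
write_tsv(eff$anova, "results/bulk_effects.tsv")
write_tsv(eff$dunnett, "results/bulk_dunnett.tsv")
sig <- eff$anova[eff$anova$p_fdr < 0.05, ]
cat("Analytes with producer effects (FDR < 0.05):\n")
print(sig[c("analyte", "diel", "F", "p_fdr")])

doc <- doc_metabolome_coupling(ft, cls, bulk, md)
write_tsv(doc, "results/doc_coupling.tsv")
cat("\nDOC coupling with metabolite pools:\n")
print(doc)
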
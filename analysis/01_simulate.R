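#!/usr/bin/env Rscript
# Generate the default synthetic incubation experiment (42 water samples +
# 8 process blanks, 870 features with planted classes) and write its four
# input tables plus the truth labels.

suppressMessages(library(reefexo))

seed <- 1
sim <- generate_experiment(sim_config(seed = seed))
dir <- "results/simulated"
write_experiment(sim, dir)

cat("Simulated experiment (seed", seed, ") written to", dir, "\n")
cat(sprintf("  %d features x %d samples\n", nrow(sim$features$areas),
            ncol(sim$features$areas)))
print(table(sim$truth$planted_class))
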
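#!/usr/bin/env Rscript

# Generates the synthetic screening benchmark used by the later scripts:
# a 281-active / 8677-decoy score table (three scoring functions with true
# AUC 0.86 / 0.77 / 0.66, 1 active + 22 decoys undocked) and SDF pose pairs
# whose RMSDs equal the published CDOCKER re-docking values. The fixture is
# byte-identical per seed; it lives under scratch/ because it is large and
# fully regenerable.

suppressMessages(library(screeneval))

seed <- 20260924L
paths <- gen_benchmark_suite("scratch/fixtures", seed = seed)
tab <- read_score_table(paths$scores)

cat("Synthetic benchmark written to scratch/fixtures (seed", seed, "):\n")
cat(sprintf("  %d ligands: %d actives, %d decoys\n", nrow(tab),
            sum(tab$label == "active"), sum(tab$label == "decoy")))
cat(sprintf("  undocked: %d (%d active, %d decoy); docked: %d\n",
            sum(!tab$docked), sum(!tab$docked & tab$label == "active"),
            sum(!tab$docked & tab$label == "decoy"), sum(tab$docked)))
cat(sprintf("  pose pairs: 22 (reference.sdf / docked.sdf)\n"))
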
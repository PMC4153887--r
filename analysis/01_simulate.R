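#!/usr/bin/env Rscript
# Simulate the three-genome synthetic campaign and write FASTA + GFF3 +
# truth JSON per genome. Every later script regenerates the same trio
# deterministically from the shared seed, so this step exists to put the
# inputs on disk for inspection.

source("analysis/00_config.R")

dir.create(SIM_DIR, showWarnings = FALSE, recursive = TRUE)
trio <- load_trio()
for (nm in names(trio)) {
  paths <- write_synthetic(trio[[nm]], SIM_DIR)
  message(sprintf("%-12s -> %s (%s bp, %d features, %d planted signals)",
                  nm, paths[["fasta"]],
                  format(trio[[nm]]$genome$length, big.mark = ","),
                  nrow(trio[[nm]]$features),
                  length(trio[[nm]]$truth$planted)))
}
message("Simulated trio written to ", SIM_DIR)
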
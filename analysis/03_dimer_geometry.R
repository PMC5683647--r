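#!/usr/bin/env Rscript
# Measure the simulated dimer models: helix-axis angles, inter-chain
# C-alpha distances, and pairwise superposition RMSDs.

suppressPackageStartupMessages(library(huihf))
paths <- Sys.glob("results/model_*.pdb")
message(length(paths), " models")

aligned <- core_aligned_seq("consensus", hu_consensus_default)
models <- lapply(paths, function(p) {
  m <- read_model(readChar(p, file.size(p)),
                  model_id = sub("model_(.*)\\.pdb", "\\1", basename(p)))
  map_core(m, aligned)
})
reports <- lapply(models, geometry_report)
tab <- geometry_table(reports, "results/geometry_report.tsv")
print(tab, digits = 4)

message("-- pairwise superposition RMSD (nm) --")
nm <- vapply(models, `[[`, character(1), "model_id")
rmsd <- matrix(0, length(models), length(models), dimnames = list(nm, nm))
for (i in seq_along(models)) for (j in seq_along(models)) {
  if (i < j) rmsd[i, j] <- rmsd[j, i] <- superpose_rmsd(models[[i]],
                                                        models[[j]])
}
write.table(round(rmsd, 4), "results/rmsd_matrix.tsv", sep = "\t",
            quote = FALSE)
print(round(rmsd, 3))
message("done")
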
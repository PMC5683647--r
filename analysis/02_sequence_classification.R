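#!/usr/bin/env Rscript
# Classify the simulated families: build per-clade score profiles, assign
# every sequence to a group/clade, embed the Fitch distance matrix by PCA,
# and census indel hotspots and terminal-extension composition.

suppressPackageStartupMessages(library(huihf))
seqs <- read_core_table("results/core_table.tsv")
message(length(seqs), " sequences read")

clades <- split(seqs, vapply(seqs, `[[`, character(1), "clade"))
groups <- setNames(rep("HU", length(clades)), names(clades))
groups[grep("clade_2", names(groups))] <- "IHF_A"
groups[grep("clade_3", names(groups))] <- "IHF_B"
profs <- lapply(names(clades), function(nm)
  build_profile(clades[[nm]], name = nm, group = groups[[nm]]))

assign <- do.call(rbind, lapply(seqs, function(s) {
  cl <- classify_sequence(s, profs)
  data.frame(id = s$id, true_clade = s$clade, called_clade = cl$clade,
             called_group = cl$group, margin = cl$margin,
             ambiguous = cl$ambiguous)
}))
write.table(assign, "results/classification.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
acc <- mean(assign$true_clade == assign$called_clade)
message(sprintf("clade assignment accuracy: %.1f%% (%d ambiguous)",
                100 * acc, sum(assign$ambiguous)))

message("-- pairwise identities and embedding --")
idm <- core_identity_matrix(seqs)
write.table(idm, "results/identity_matrix.tsv", sep = "\t", quote = FALSE)
dm <- fitch_distance(seqs)
emb <- pca_embed(dm, k = 3)
coords <- data.frame(id = emb$ids, emb$coords,
                     clade = vapply(seqs, `[[`, character(1), "clade"))
write.table(coords, "results/pca_embedding.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("first three components explain %.0f%% / %.0f%% / %.0f%% of variance",
                100 * emb$explained[1], 100 * emb$explained[2],
                100 * emb$explained[3]))

message("-- indel census --")
cen <- indel_census(seqs)
write.table(cen$table, "results/indel_census.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(cen)

message("-- terminal extensions --")
term <- do.call(rbind, lapply(seqs, function(s) {
  st <- terminal_stats(s, "C")
  if (st$length == 0) return(NULL)
  data.frame(id = s$id, clade = s$clade, length = st$length,
             K = st$count_K, R = st$count_R, D = st$count_D, E = st$count_E,
             pakka = length(st$pakka_hits))
}))
if (!is.null(term)) {
  write.table(term, "results/terminal_stats.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("C-terminal extensions: mean length %.0f, mean %.1f K, %.1f R, %.1f PAKKA repeats",
                  mean(term$length), mean(term$K), mean(term$R),
                  mean(term$pakka)))
}
message("done")
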
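#!/usr/bin/env Rscript
# Assemble the oligonucleotide constructs: the D-48 truncation series used
# for site-size ladders and the panel of distorted-DNA structures
# (nick, bulges, overhang, fork, junction, incomplete junction, invasion).

suppressPackageStartupMessages(library(huihf))
d48 <- oligo_d48()

message("-- truncation series 20-48 bp --")
series <- truncation_series(d48, 20:48)
series_tab <- data.frame(
  name = names(series),
  length = vapply(series, function(a) sum(a$segments$length), integer(1)),
  label = vapply(series, classify_structure, character(1)))
write.table(series_tab, "results/truncation_series.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(nrow(series_tab), " duplexes, all classified ",
        paste(unique(series_tab$label), collapse = "/"))

message("-- distorted-structure panel --")
P <- substr(d48$sequence, 1, 24); Q <- substr(d48$sequence, 25, 48)
comp <- revcomp(d48$sequence)
arm_r <- "GGATCAGTTCAGGATCCATTGGAC"
arm_s <- "CCTTAGTTCCGGTTAACGGTTCAC"
bulge <- function(m) oligo(paste0("comp+A", m),
                           paste0(substr(comp, 1, 24), strrep("A", m),
                                  substr(comp, 25, 48)))
panel <- list(
  ds   = list(d48, oligo("D-48c", comp)),
  n    = list(d48, oligo("L24", revcomp(P)), oligo("R24", revcomp(Q))),
  A1   = list(d48, bulge(1)),
  A3   = list(d48, bulge(3)),
  A7   = list(d48, bulge(7)),
  ov   = list(d48, oligo("J24.rgt", "ACTCAACTGCACTCTAGACT")),
  fork = list(d48, oligo("forkarm",
                         paste0("GGATGGTTGGTAGGATTGGATTGG", revcomp(P)))),
  J    = list(d48, oligo("s2", paste0(revcomp(Q), arm_r)),
              oligo("s3", paste0(revcomp(arm_r), arm_s)),
              oligo("s4", paste0(revcomp(arm_s), revcomp(P)))),
  iJ   = list(d48, oligo("s2", paste0(revcomp(Q), arm_r)),
              oligo("s4", paste0(revcomp(arm_s), revcomp(P)))),
  inv  = list(d48, oligo("F36", revcomp(substr(d48$sequence, 1, 36))),
              oligo("V24", revcomp(Q)))
)
panel_tab <- do.call(rbind, lapply(names(panel), function(nm) {
  a <- anneal(panel[[nm]])
  data.frame(construct = nm, n_oligos = length(panel[[nm]]),
             called = classify_structure(a),
             paired_bp = sum(a$segments$length))
}))
write.table(panel_tab, "results/construct_panel.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(panel_tab)
stopifnot(panel_tab$construct == panel_tab$called)
message("all ", nrow(panel_tab), " constructs classify as designed")
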
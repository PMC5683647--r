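#!/usr/bin/env Rscript
# Quantitative binding analysis: site-size ladders, cooperativity fits of
# the simulated titrations, and a dsDNA-normalised structure-specific
# affinity profile.

suppressPackageStartupMessages(library(huihf))
phen <- read.delim("results/phenotypes.tsv")

message("-- binding-site sizes from length ladders --")
ladder_tab <- do.call(rbind, lapply(seq_len(nrow(phen)), function(i) {
  lad <- generate_ladder(n = phen$n[i], K = 1e7,
                         omega = max(1, phen$omega[i]), lengths = 20:48)
  est <- estimate_site_size(lad)
  data.frame(protein = phen$protein[i], true_n = phen$n[i],
             estimated_n = est$n, offset = est$offset,
             mismatches = est$mismatches)
}))
write.table(ladder_tab, "results/site_sizes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(ladder_tab)

message("-- cooperativity fits (with bootstrap CI) --")
fit_tab <- do.call(rbind, lapply(seq_len(nrow(phen)), function(i) {
  tt <- read_titration(sprintf("results/titration_%s.tsv", phen$protein[i]))
  fit <- fit_cooperative(tt, n_fixed = phen$n[i], n_boot = 100,
                         seed = 900 + i)
  data.frame(protein = phen$protein[i], true_omega = phen$omega[i],
             Kd_nM = fit$Kd * 1e9, omega = fit$omega,
             omega_lo = fit$omega_ci[1], omega_hi = fit$omega_ci[2])
}))
write.table(fit_tab, "results/cooperativity_fits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(fit_tab, digits = 3)

message("-- structure-specific affinity profile --")
# simulate single-band titrations of the construct panel at 10.5 nM DNA
# with structure-dependent Kd ratios (junction-preferring phenotype),
# then re-fit and normalise to the dsDNA reference
set.seed(31)
true_rel <- c(ds = 1, n = 1.6, A1 = 2.2, A3 = 3.5, A7 = 5.5,
              J = 12, fork = 4.5, ov = 1.3, iJ = 7, inv = 6)
Kd_ds <- 120e-9
D_t <- 10.5e-9
P_t <- c(10, 25, 50, 100, 200, 400, 800, 1600) * 1e-9
fits <- lapply(names(true_rel), function(st) {
  Kd <- Kd_ds / true_rel[[st]]
  s <- P_t + D_t + Kd
  frac <- ((s - sqrt(s^2 - 4 * P_t * D_t)) / 2) / D_t
  frac <- pmin(pmax(frac + rnorm(length(frac), 0, 0.02), 0), 1)
  fit_kd_single_site(P_t, frac, D_t)
})
names(fits) <- names(true_rel)
prof <- affinity_profile(fits)
prof$true_rel_Ka <- unname(true_rel[prof$structure])
write.table(prof, "results/affinity_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(prof, digits = 3)
message(sprintf("junction preference recovered: rel_Ka(J)/rel_Ka(ds) = %.1f (true %.1f)",
                prof$rel_Ka[prof$structure == "J"], true_rel[["J"]]))
message("done")
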
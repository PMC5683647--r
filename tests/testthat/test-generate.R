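test_that("generators are deterministic under a fixed seed", {
  s1 <- generate_family(seq_family_spec(n_sequences = 5, seed = 42))
  s2 <- generate_family(seq_family_spec(n_sequences = 5, seed = 42))
  expect_identical(s1, s2)
  g1 <- generate_dimer(dimer_geom_spec(seed = 42))
  g2 <- generate_dimer(dimer_geom_spec(seed = 42))
  expect_identical(g1$pdb, g2$pdb)
  truth <- lattice_model(9, 1e7, 12, 48)
  sp <- emsa_sim_spec(truth, protein_totals = c(1, 2, 4, 8) * 1e-7, seed = 42)
  expect_identical(generate_emsa(sp)$fractions, generate_emsa(sp)$fractions)
})

test_that("perfect identity with no indels reproduces the consensus", {
  fam <- generate_family(seq_family_spec(n_sequences = 5, identity = 1,
                                         p_insert = 0, p_delete = 0,
                                         seed = 1))
  for (s in fam) expect_identical(s$core, hu_consensus_default)
})

test_that("the family identity target is hit on average", {
  # identity 62/90 = 0.689: mean identity to the consensus within +-2 columns
  fam <- generate_family(seq_family_spec(n_sequences = 50, identity = 62 / 90,
                                         p_insert = 0, p_delete = 0,
                                         seed = 31))
  cons <- core_seq(hu_consensus_default)
  ids <- vapply(fam, function(s) core_identity(s, cons), integer(1))
  expect_lt(abs(mean(ids) - 62), 2)
})

test_that("generated sequences satisfy the reconstruction invariant", {
  fam <- generate_family(seq_family_spec(
    n_sequences = 30, identity = 0.7, p_insert = 0.5, p_delete = 0.3,
    seed = 8,
    n_ext_spec = list(length = 15, count_K = 4, count_R = 1, count_D = 1,
                      count_E = 1, pakka_n = 1)))
  for (s in fam) expect_identical(reconstruct_raw(s), s$raw_seq)
})

test_that("noise-free simulated fractions equal the model probabilities", {
  truth <- lattice_model(9, 1e7, 0.25, 48)
  pt <- c(1, 2, 4, 8, 16) * 1e-7
  tt <- generate_emsa(emsa_sim_spec(truth, protein_totals = pt,
                                    noise_sd = 0, seed = 1))
  pred <- predict_titration(truth, 200e-9, pt)
  expect_equal(unname(tt$fractions), unname(unclass(pred)[, ]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the site-size ladder increments every n bp", {
  lad <- generate_ladder(n = 9, K = 1e7, omega = 1, lengths = 20:48)
  expect_identical(lad$max_complexes, as.integer(20:48 %/% 9))
  steps <- diff(lad$max_complexes)
  expect_true(all(steps %in% c(0L, 1L)))
  expect_identical(lad$dna_length[which(steps == 1L) + 1L], c(27L, 36L, 45L))
})

test_that("full pipeline: families -> profiles -> classification recovers clades", {
  fams <- generate_clade_set(n_clades = 3, n_per_clade = 20,
                             interclade_identity = 0.65,
                             intraclade_identity = 0.85, seed = 202)
  groups <- c("HU", "IHF_A", "IHF_B")
  profs <- lapply(1:3, function(k)
    build_profile(fams[[k]], name = names(fams)[k], group = groups[k]))
  correct <- 0; total <- 0
  for (k in 1:3) for (s in fams[[k]]) {
    total <- total + 1
    correct <- correct + (classify_sequence(s, profs)$clade == names(fams)[k])
  }
  expect_gte(correct / total, 0.99)
})
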
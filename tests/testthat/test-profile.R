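test_that("identical members give full conservation and their own consensus", {
  core <- random_core(31)
  p <- build_profile(lapply(1:5, function(i) core_seq(core, id = paste0("s", i))))
  expect_identical(p$consensus, core)
  expect_true(all(p$conservation == 1))
  expect_true(all(abs(rowSums(p$freq) - 1) < 1e-9))
})

test_that("a 50/50 column ties to the lexicographically smaller residue", {
  half1 <- core_seq(paste0("W", strrep("A", 89)), id = "a")
  half2 <- core_seq(paste0("C", strrep("A", 89)), id = "b")
  p <- build_profile(list(half1, half2))
  expect_identical(substr(p$consensus, 1, 1), "C")
  expect_equal(p$conservation[1], 0.5)
})

test_that("the generating consensus is recovered from mutated members", {
  fam <- generate_family(seq_family_spec(n_sequences = 10, identity = 0.9,
                                         p_insert = 0, p_delete = 0,
                                         seed = 101))
  p <- build_profile(fam)
  agree <- sum(strsplit(p$consensus, "")[[1]] ==
               strsplit(hu_consensus_default, "")[[1]])
  expect_gte(agree, 85)
})

test_that("per-column frequencies sum to one with any pseudocount", {
  fam <- generate_family(seq_family_spec(n_sequences = 6, identity = 0.7,
                                         seed = 41))
  for (pc in c(0.1, 0.5, 2)) {
    p <- build_profile(fam, pseudocount = pc)
    expect_true(all(abs(rowSums(p$freq) - 1) < 1e-9))
  }
})

test_that("a consensus classifies to its own profile with positive margin", {
  fams <- generate_clade_set(n_clades = 2, n_per_clade = 10,
                             interclade_identity = 0.6, seed = 5)
  profs <- list(build_profile(fams[[1]], name = "clade_1", group = "HU"),
                build_profile(fams[[2]], name = "clade_2", group = "IHF_A"))
  cl <- classify_sequence(core_seq(profs[[1]]$consensus), profs)
  expect_identical(cl$clade, "clade_1")
  expect_identical(cl$group, "HU")
  expect_gt(cl$margin, 0)
  expect_false(cl$ambiguous)
})

test_that("equal scores on duplicated profiles are flagged ambiguous", {
  fam <- generate_family(seq_family_spec(n_sequences = 8, identity = 0.8,
                                         seed = 3))
  p1 <- build_profile(fam, name = "p1", group = "HU")
  p2 <- build_profile(fam, name = "p2", group = "IHF_B")
  cl <- classify_sequence(fam[[1]], list(p1, p2))
  expect_equal(cl$margin, 0)
  expect_true(cl$ambiguous)
  expect_error(classify_sequence(fam[[1]], list()), "empty")
})

test_that("members of generating clades are assigned to them without error", {
  fams <- generate_clade_set(n_clades = 3, n_per_clade = 15,
                             interclade_identity = 0.6,
                             intraclade_identity = 0.85, seed = 77)
  groups <- c("HU", "IHF_A", "IHF_B")
  profs <- lapply(1:3, function(k)
    build_profile(fams[[k]], name = names(fams)[k], group = groups[k]))
  hits <- 0; total <- 0
  for (k in 1:3) for (s in fams[[k]]) {
    cl <- classify_sequence(s, profs)
    total <- total + 1
    hits <- hits + (cl$clade == names(fams)[k])
  }
  expect_identical(hits, total)  # 100% correct assignment
})
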
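test_that("noise-free titrations return the generating parameters", {
  for (om_true in c(0.25, 12)) {
    truth <- lattice_model(n = 9, K = 1e7, omega = om_true, N = 48)
    pt <- design_titration(truth, 200e-9)
    t0 <- generate_emsa(emsa_sim_spec(truth, protein_totals = pt,
                                      noise_sd = 0, seed = 1))
    fit <- fit_cooperative(t0, n_fixed = 9)
    expect_equal(fit$omega, om_true, tolerance = 1e-3 / om_true)
    expect_equal(fit$Ka, 1e7, tolerance = 1e-3)
  }
})

test_that("omega fixed to 1 on non-cooperative data recovers K within 1%", {
  truth <- lattice_model(n = 9, K = 5e6, omega = 1, N = 48)
  pt <- design_titration(truth, 200e-9)
  t0 <- generate_emsa(emsa_sim_spec(truth, protein_totals = pt,
                                    noise_sd = 0, seed = 2))
  fit <- fit_cooperative(t0, n_fixed = 9, omega_fixed = 1)
  expect_equal(fit$Ka, 5e6, tolerance = 0.01)
})

test_that("uninformative titrations are rejected as non-identifiable", {
  truth <- lattice_model(n = 9, K = 1e7, omega = 1, N = 48)
  # all free
  tf <- generate_emsa(emsa_sim_spec(truth, protein_totals = rep(1e-12, 5),
                                    noise_sd = 0, seed = 1))
  expect_error(fit_cooperative(tf, n_fixed = 9), "non-identifiable")
  # all saturated
  ts <- generate_emsa(emsa_sim_spec(truth, protein_totals = rep(5e-4, 5),
                                    noise_sd = 0, seed = 1))
  expect_error(fit_cooperative(ts, n_fixed = 9), "non-identifiable")
})

test_that("bootstrap CI covers the generating omega in most replicates", {
  truth <- lattice_model(n = 9, K = 1e7, omega = 12, N = 48)
  pt <- design_titration(truth, 200e-9)
  hits <- 0
  for (b in 1:10) {
    tt <- generate_emsa(emsa_sim_spec(truth, protein_totals = pt,
                                      noise_sd = 0.02, seed = 300 + b))
    fit <- fit_cooperative(tt, n_fixed = 9, n_boot = 30, seed = b)
    if (fit$omega_ci[1] <= 12 && 12 <= fit$omega_ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("site size is recovered from every noise-free ladder, n = 8..12", {
  for (n_true in 8:12) {
    lad <- generate_ladder(n = n_true, K = 1e7, omega = 1, lengths = 20:48)
    est <- estimate_site_size(lad)
    expect_identical(est$n, n_true)
    expect_identical(est$mismatches, 0L)
    expect_identical(est$tied_n, n_true)
  }
})

test_that("the single-step ladder pattern brackets the site size at 9-10 bp", {
  # two complexes at 21-28 bp, a third appearing from 29 bp
  lad <- data.frame(dna_length = 21:36,
                    max_complexes = c(rep(2L, 8), rep(3L, 8)))
  est <- estimate_site_size(lad)
  expect_true(est$n %in% c(9L, 10L))
  expect_identical(est$mismatches, 0L)
})

test_that("constant complex counts are non-identifiable", {
  lad <- data.frame(dna_length = 20:30, max_complexes = rep(2L, 11))
  expect_error(estimate_site_size(lad), "non-identifiable")
})

test_that("single-site Kd fitting with depletion recovers the truth", {
  Kd <- 50e-9; D <- 10.5e-9
  P <- c(10, 25, 50, 100, 200, 400) * 1e-9
  s <- P + D + Kd
  frac <- ((s - sqrt(s^2 - 4 * P * D)) / 2) / D
  fit <- fit_kd_single_site(P, frac, D)
  expect_equal(fit$Kd, Kd, tolerance = 1e-3)
  # weak-depletion limit: half saturation at P = Kd
  f_half <- fit_kd_single_site(c(Kd / 8, Kd / 2, Kd, 2 * Kd, 8 * Kd),
                               c(1 / 9, 1 / 3, 1 / 2, 2 / 3, 8 / 9), 1e-12)
  expect_equal(f_half$Kd, Kd, tolerance = 0.01)
  expect_error(fit_kd_single_site(P, frac + 0.5, D), "outside")
  expect_error(fit_kd_single_site(P, rep(0.99, 6), D), "non-identifiable")
})

test_that("affinity profiles are normalised to the dsDNA reference", {
  mk <- function(Kd) structure(list(Kd = Kd, Ka = 1 / Kd),
                               class = "binding_fit")
  fits <- list(ds = mk(1e-7), J = mk(2e-8), fork = mk(1e-7))
  prof <- affinity_profile(fits)
  expect_equal(prof$rel_Ka[prof$structure == "ds"], 1)
  expect_equal(prof$rel_Ka[prof$structure == "J"], 5)
  expect_equal(prof$rel_Ka[prof$structure == "fork"], 1)
  expect_error(affinity_profile(list(J = mk(1e-8))), "ds")
})
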
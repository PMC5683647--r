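test_that("PDB round trip: two chains, waters ignored, errors on monomers", {
  g <- generate_dimer(dimer_geom_spec(seed = 9))
  m <- read_model(g$pdb)
  expect_length(m$chains, 2L)
  expect_identical(nrow(m$chains[[1]]), 90L)
  expect_identical(nrow(m$chains[[2]]), 90L)
  # HETATM waters are ignored
  with_water <- sub("END", "HETATM 9999  O   HOH A 500      10.000  10.000  10.000  1.00  0.00           O\nEND",
                    g$pdb)
  m2 <- read_model(with_water)
  expect_identical(nrow(m2$chains[[1]]), 90L)
  # single chain is not a dimer
  lines <- strsplit(g$pdb, "\n")[[1]]
  single <- paste(c(lines[grepl(" A ", lines, fixed = TRUE)], "END"),
                  collapse = "\n")
  expect_error(read_model(single), "expected dimer")
})

test_that("core mapping handles extensions and gap columns", {
  g <- generate_dimer(dimer_geom_spec(seed = 10))
  m <- read_model(g$pdb)
  cons <- hu_consensus_default
  # gapless core: residue i maps to column i
  m1 <- map_core(m, core_seq(cons))
  expect_identical(m1$chains[[1]]$column, 1:90)
  # N-terminal extension: first 6 residues unmapped, residue 7 is column 1
  g6 <- generate_dimer(dimer_geom_spec(seed = 10),
                       sequence = cons)  # model sequence unchanged
  ext_seq <- core_seq(cons, n_ext = "MSKDLI")
  m_ext <- read_model(g6$pdb)
  m_ext$chains <- lapply(m_ext$chains, function(ch) {
    pre <- ch[1:6, ]
    pre$aa <- strsplit("MSKDLI", "")[[1]]
    pre$resno <- -5:0
    out <- rbind(pre, ch)
    out$resno <- seq_len(nrow(out))
    out
  })
  m_ext <- map_core(m_ext, ext_seq)
  expect_true(all(is.na(m_ext$chains[[1]]$column[1:6])))
  expect_identical(m_ext$chains[[1]]$column[7], 1L)
  # gap at column 15: columns jump 14 -> 16
  gap_core <- paste0(substr(cons, 1, 14), "-", substr(cons, 16, 90))
  gap_seq <- core_seq(gap_core)
  m_gap <- read_model(g$pdb)
  m_gap$chains <- lapply(m_gap$chains, function(ch) {
    ch <- ch[1:89, ]
    ch$aa <- strsplit(gap_seq$raw_seq, "")[[1]]
    ch$resno <- 1:89
    ch
  })
  m_gap <- map_core(m_gap, gap_seq)
  expect_identical(m_gap$chains[[1]]$column[14:15], c(14L, 16L))
  # sequence mismatch reports the first offending position
  expect_error(map_core(m, core_seq(paste0("W", substr(cons, 2, 90)))),
               "position 1")
})

test_that("helix axis fitting recovers known directions", {
  h <- test_helix(36)  # 10 exact turns: principal axis is exactly z
  ax <- fit_axis(h)
  expect_equal(ax$direction, c(0, 0, 1), tolerance = 1e-6)
  # rotated helix: axis follows the rotation
  set.seed(12)
  for (i in 1:5) {
    R <- rot_about(rnorm(3), runif(1, 0, pi))
    ax_r <- fit_axis(h %*% t(R))
    target <- as.numeric(R %*% c(0, 0, 1))
    expect_equal(abs(sum(ax_r$direction * target)), 1, tolerance = 1e-9)
  }
  expect_error(fit_axis(h[1:4, ]), "at least 5")
  expect_error(fit_axis(matrix(rep(c(1, 2, 3), 6), 6, 3, byrow = TRUE)),
               "degenerate")
})

test_that("interaxis angles are undirected, bounded and rigid-motion invariant", {
  mk <- function(d) structure(list(direction = d / sqrt(sum(d^2)),
                                   centroid = c(0, 0, 0)),
                              class = "helix_axis")
  expect_equal(interaxis_angle(mk(c(0, 0, 1)), mk(c(0, 0, 1))), 0)
  expect_equal(interaxis_angle(mk(c(0, 0, 1)), mk(c(0, 0, -1))), 0)
  expect_equal(interaxis_angle(mk(c(1, 0, 0)), mk(c(0, 1, 0))), 90)
  set.seed(4)
  for (i in 1:10) {
    u <- rnorm(3); v <- rnorm(3)
    a0 <- interaxis_angle(mk(u), mk(v))
    expect_gte(a0, 0); expect_lte(a0, 90)
    R <- rot_about(rnorm(3), runif(1, 0, 2 * pi))
    a1 <- interaxis_angle(mk(as.numeric(R %*% u)), mk(as.numeric(R %*% v)))
    expect_equal(a0, a1, tolerance = 1e-9)
    expect_equal(interaxis_angle(mk(-u), mk(v)), a0, tolerance = 1e-9)
  }
})

test_that("generated dimers reproduce their target geometry", {
  set.seed(20)
  for (i in 1:20) {
    spec <- dimer_geom_spec(
      angle_a1a2 = runif(1, 50, 70), angle_a2a3 = runif(1, 55, 70),
      angle_a2a2_cross = runif(1, 75, 89), dist_h2C = runif(1, 3.0, 3.6),
      dist_b2 = runif(3, 2.2, 3.2), dist_b5 = runif(3, 2.4, 3.6),
      seed = 100 + i)
    r <- geometry_report(generate_dimer(spec)$model)
    expect_equal(unname(r$angle_a1a2), rep(spec$angle_a1a2, 2),
                 tolerance = 0.5 / spec$angle_a1a2)
    expect_equal(unname(r$angle_a2a3), rep(spec$angle_a2a3, 2),
                 tolerance = 0.5 / spec$angle_a2a3)
    expect_equal(r$angle_a2a2_cross, spec$angle_a2a2_cross,
                 tolerance = 0.5 / spec$angle_a2a2_cross)
    expect_equal(r$dist_h2C, spec$dist_h2C, tolerance = 0.01 / spec$dist_h2C)
    expect_equal(unname(r$dist_b2), spec$dist_b2, tolerance = 0.005)
    expect_equal(unname(r$dist_b5), spec$dist_b5, tolerance = 0.005)
    # homodimer symmetry: per-monomer angles equal between chains
    expect_equal(r$angle_a1a2[1], r$angle_a1a2[2], tolerance = 1e-9)
  }
})

test_that("reported angles stay inside [0, 90] including family ranges", {
  r <- geometry_report(generate_dimer(dimer_geom_spec(seed = 2))$model)
  angs <- c(r$angle_a1a2, r$angle_a2a3, r$angle_a2a2_cross)
  expect_true(all(angs >= 0 & angs <= 90))
  # family-wide printed ranges fall inside the convention bound
  expect_true(all(c(55.8, 66.8, 82.0, 85.0) <= 90))
})

test_that("an undersized span yields NA measurements, not fabrications", {
  g <- generate_dimer(dimer_geom_spec(seed = 30))
  m <- g$model
  # unmap most of helix 1 in both chains
  for (ci in 1:2) {
    sel <- m$chains[[ci]]$column %in% 4:13
    m$chains[[ci]]$column[sel] <- NA_integer_
  }
  r <- geometry_report(m)
  expect_true(all(is.na(r$angle_a1a2)))
  expect_false(anyNA(r$angle_a2a3))
})

test_that("superposition RMSD matches the quaternion oracle and is symmetric", {
  g <- generate_dimer(dimer_geom_spec(seed = 40))
  m <- map_core(read_model(g$pdb), core_seq(hu_consensus_default))
  expect_equal(superpose_rmsd(m, m), 0, tolerance = 1e-12)
  # rigid motion: still zero
  m_rt <- m
  R <- rot_about(c(1, 2, 3), 1.1)
  for (ci in 1:2) {
    xyz <- as.matrix(m_rt$chains[[ci]][, c("x", "y", "z")]) %*% t(R)
    m_rt$chains[[ci]]$x <- xyz[, 1] + 2
    m_rt$chains[[ci]]$y <- xyz[, 2] - 1
    m_rt$chains[[ci]]$z <- xyz[, 3] + 0.5
  }
  expect_equal(superpose_rmsd(m, m_rt), 0, tolerance = 1e-9)
  # displaced atom: compare against the independent quaternion oracle
  m_d <- m_rt
  m_d$chains[[1]]$x[50] <- m_d$chains[[1]]$x[50] + 0.3
  P <- rbind(as.matrix(m$chains[[1]][, c("x", "y", "z")]),
             as.matrix(m$chains[[2]][, c("x", "y", "z")]))
  Q <- rbind(as.matrix(m_d$chains[[1]][, c("x", "y", "z")]),
             as.matrix(m_d$chains[[2]][, c("x", "y", "z")]))
  expect_equal(superpose_rmsd(m, m_d), quaternion_rmsd(P, Q),
               tolerance = 1e-9)
  expect_equal(superpose_rmsd(m, m_d), superpose_rmsd(m_d, m),
               tolerance = 1e-9)
  expect_error(superpose_rmsd(m, m_d, columns = 1:2), "at least 3")
})
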
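# Independent oracles and fixture builders used across the suite.

# Exhaustive enumeration of ligand configurations on a finite lattice:
# depth-first over admissible start positions, accumulating
# x^k * omega^contacts per configuration. Independent of the package's
# transfer-matrix recursion.
enumerate_lattice_pk <- function(N, n, x, omega) {
  kmax <- N %/% n
  w <- numeric(kmax + 1)
  recurse <- function(next_free, k, contacts, last_end) {
    w[k + 1] <<- w[k + 1] + x^k * omega^contacts
    if (next_free + n - 1 > N) return(invisible())
    for (s in next_free:(N - n + 1)) {
      recurse(s + n, k + 1,
              contacts + as.integer(!is.na(last_end) && s == last_end + 1),
              s + n - 1)
    }
  }
  recurse(1, 0, 0, NA_integer_)
  w / sum(w)
}

# Quaternion (Horn 1987) superposition oracle: minimal RMSD from the
# largest eigenvalue of the 4x4 key matrix; no rotation matrix built.
quaternion_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  S <- crossprod(Pc, Qc)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lambda) / nrow(P)
  sqrt(max(0, msd))
}

# random 90-column core with no gaps
random_core <- function(seed = 1) {
  set.seed(seed)
  paste(sample(AA_ALPHABET, 90, replace = TRUE), collapse = "")
}

core_seq <- function(core, id = "s", ...) core_aligned_seq(id, core, ...)

# random DNA of given length avoiding self-complementary runs >= minrun
random_oligo_seq <- function(len, minrun = 8, max_tries = 200) {
  for (i in seq_len(max_tries)) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    rc <- revcomp(s)
    # longest common substring between s and its own revcomp
    ok <- TRUE
    for (start in seq_len(len - minrun + 1)) {
      if (grepl(substr(s, start, start + minrun - 1), rc, fixed = TRUE)) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(s)
  }
  stop("could not draw a non-self-complementary oligo")
}

# rotation matrix about a unit axis by angle (radians)
rot_about <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  Kx <- matrix(c(0, -axis[3], axis[2],
                 axis[3], 0, -axis[1],
                 -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * Kx + (1 - cos(theta)) * (Kx %*% Kx)
}

# ideal CA helix used by axis tests (36 residues = 10 exact turns at
# 100 deg/residue, so the principal axis is exactly the helix axis)
test_helix <- function(n_res = 36, rise = 0.15, radius = 0.23,
                       twist = 100, phase = 0) {
  k <- seq_len(n_res) - 1
  th <- phase + k * twist * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * k)
}
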
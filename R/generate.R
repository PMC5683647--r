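#' Specification for a synthetic core-aligned sequence family
#'
#' Defaults reflect the indel statistics of natural HU families: about 10%
#' of sequences carry an insert, 80% of inserts are single residues, and
#' insert positions concentrate in the helix-1/2 loop (34%), the
#' helix-2/strand-1 turn (18%) and the DNA-binding arm tip (15%).
#'
#' @param consensus 90-residue consensus string.
#' @param n_sequences family size.
#' @param identity expected per-column identity to the consensus (0, 1].
#' @param p_insert probability a sequence carries one insertion event.
#' @param region_weights named weights (`loop_a1_a2`, `turn_a2_b1`,
#'   `arm_tip`, `other`) summing to 1.
#' @param insert_p1 probability an insert is a single residue; longer
#'   inserts extend geometrically.
#' @param p_delete probability of one deletion run (1-3 columns).
#' @param c_ext_spec,n_ext_spec optional terminal specification: list with
#'   `length`, `count_K`, `count_R`, `count_D`, `count_E`, `pakka_n`.
#' @param clade,group annotations applied to every member.
#' @param id_prefix member id prefix.
#' @param seed integer seed.
#' @return object of class `seq_family_spec`.
#' @export
seq_family_spec <- function(consensus = hu_consensus_default,
                            n_sequences = 20, identity = 0.85,
                            p_insert = 0.10,
                            region_weights = c(loop_a1_a2 = 0.34,
                                               turn_a2_b1 = 0.18,
                                               arm_tip = 0.15,
                                               other = 0.33),
                            insert_p1 = 0.8, p_delete = 0.05,
                            n_ext_spec = NULL, c_ext_spec = NULL,
                            clade = "synthetic", group = "HU",
                            id_prefix = "syn", seed = 1L) {
  stopifnot(nchar(consensus) == 90L, identity > 0, identity <= 1,
            abs(sum(region_weights) - 1) < 1e-9)
  structure(as.list(environment()), class = "seq_family_spec")
}

# exact-composition terminal extension; filler residues exclude P and the
# charged set so the planted PAKKA motifs are the only ones present
make_terminal <- function(spec) {
  pakka_n <- spec$pakka_n %||% 0L
  k_extra <- spec$count_K - 2L * pakka_n
  if (k_extra < 0) stop("count_K smaller than lysines in PAKKA repeats")
  n_single <- spec$length - 5L * pakka_n
  n_fill <- n_single - k_extra - spec$count_R - spec$count_D - spec$count_E
  if (n_fill < 0) stop("terminal length too short for requested composition")
  filler <- c("A", "G", "S", "T", "N", "Q", "F", "L", "I", "V")
  units <- c(rep("PAKKA", pakka_n),
             rep("K", k_extra), rep("R", spec$count_R),
             rep("D", spec$count_D), rep("E", spec$count_E),
             sample(filler, n_fill, replace = TRUE))
  paste(sample(units), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic core-aligned sequence family
#'
#' Each member is mutated i.i.d. per column at rate `1 - identity`;
#' insertion events are placed according to the region weights and
#' deletion runs at random columns; terminal extensions are appended with
#' exact composition. Fully reproducible under the spec seed.
#'
#' @param spec a [seq_family_spec()].
#' @return list of [core_aligned_seq()].
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "seq_family_spec"))
  set.seed(spec$seed)
  cons <- strsplit(spec$consensus, "")[[1]]
  regions <- default_indel_regions()
  region_cols <- lapply(regions, function(r) r[1]:r[2])
  region_cols$other <- setdiff(1:89, unlist(region_cols))
  lapply(seq_len(spec$n_sequences), function(i) {
    syms <- cons
    mut <- runif(90) > spec$identity
    if (any(mut))
      syms[mut] <- vapply(which(mut), function(cc)
        sample(setdiff(AA_ALPHABET, cons[cc]), 1L), character(1))
    if (runif(1) < spec$p_delete) {
      len <- sample(1:3, 1L)
      start <- sample(seq_len(90L - len + 1L), 1L)
      syms[start:(start + len - 1L)] <- GAP
    }
    ins <- list()
    if (runif(1) < spec$p_insert) {
      rg <- sample(names(spec$region_weights), 1L,
                   prob = spec$region_weights)
      col <- if (length(region_cols[[rg]]) == 1L) region_cols[[rg]] else
        sample(region_cols[[rg]], 1L)
      len <- if (runif(1) < spec$insert_p1) 1L else 1L + rgeom(1L, 0.5) + 1L
      ins[[as.character(col)]] <- paste(
        sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
    }
    core_aligned_seq(
      id = sprintf("%s_%03d", spec$id_prefix, i),
      core = paste(syms, collapse = ""),
      insertions = ins,
      n_ext = if (is.null(spec$n_ext_spec)) "" else
        make_terminal(spec$n_ext_spec),
      c_ext = if (is.null(spec$c_ext_spec)) "" else
        make_terminal(spec$c_ext_spec),
      group = spec$group, clade = spec$clade)
  })
}

#' Generate a set of clade-structured families
#'
#' Derives one consensus per clade by mutating a base consensus to the
#' requested inter-clade identity, then generates a family around each.
#'
#' @param n_clades number of clades.
#' @param n_per_clade members per clade.
#' @param interclade_identity identity of each clade consensus to the base.
#' @param intraclade_identity member identity to the clade consensus.
#' @param base_consensus 90-residue string.
#' @param seed integer seed.
#' @param ... further arguments passed to [seq_family_spec()].
#' @return named list of families (lists of [core_aligned_seq()]).
#' @export
generate_clade_set <- function(n_clades = 3, n_per_clade = 20,
                               interclade_identity = 0.65,
                               intraclade_identity = 0.85,
                               base_consensus = hu_consensus_default,
                               seed = 1L, ...) {
  set.seed(seed)
  base <- strsplit(base_consensus, "")[[1]]
  out <- list()
  for (k in seq_len(n_clades)) {
    syms <- base
    mut <- runif(90) > interclade_identity
    syms[mut] <- vapply(which(mut), function(cc)
      sample(setdiff(AA_ALPHABET, base[cc]), 1L), character(1))
    clade_name <- sprintf("clade_%d", k)
    spec <- seq_family_spec(consensus = paste(syms, collapse = ""),
                            n_sequences = n_per_clade,
                            identity = intraclade_identity,
                            clade = clade_name,
                            id_prefix = clade_name,
                            seed = seed + k, ...)
    out[[clade_name]] <- generate_family(spec)
  }
  out
}

# ---------------------------------------------------------------------------
# dimer geometry generator

#' Specification for a synthetic HU dimer C-alpha model
#'
#' Target measurement values (defaults are the family-wide averages of the
#' modelled HU set) plus ideal-helix parameters.
#'
#' @param angle_a1a2,angle_a2a3 intra-monomer helix-axis angles, degrees.
#' @param angle_a2a2_cross inter-monomer helix-2 angle, degrees.
#' @param dist_h2C inter-chain distance between the helix-2 C-terminal
#'   residues, nm.
#' @param dist_b2,dist_b5 inter-chain distance triples at the strand-2 end
#'   (columns 54-56) and strand-5 start (columns 73-75), nm.
#' @param rise,radius,twist ideal alpha-helix parameters (nm, nm,
#'   degrees/residue).
#' @param seed integer seed (randomises helix phases, not measurements).
#' @return object of class `dimer_geom_spec`.
#' @export
dimer_geom_spec <- function(angle_a1a2 = 62.7, angle_a2a3 = 63.7,
                            angle_a2a2_cross = 83.5, dist_h2C = 3.33,
                            dist_b2 = c(2.48, 2.9, 2.64),
                            dist_b5 = c(3.12, 2.67, 3.42),
                            rise = 0.15, radius = 0.23, twist = 100,
                            seed = 1L) {
  angs <- c(angle_a1a2, angle_a2a3, angle_a2a2_cross)
  if (any(angs <= 0 | angs >= 90))
    stop("infeasible target: angles must lie strictly inside (0, 90) degrees")
  if (any(c(dist_h2C, dist_b2, dist_b5) <= 0))
    stop("infeasible target: distances must be positive")
  structure(as.list(environment()), class = "dimer_geom_spec")
}

rotation_between <- function(u, v) {
  # rotation matrix mapping unit vector u onto unit vector v
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {  # opposite: rotate pi about any perpendicular
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * u) * u; ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  ax <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(ax^2)); ax <- ax / s
  Kx <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + s * Kx + (1 - c_) * (Kx %*% Kx)
}

ideal_helix <- function(n_res, rise, radius, twist_deg, phase = 0) {
  k <- seq_len(n_res) - 1
  th <- phase + k * twist_deg * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * k)
}

# place an ideal helix so that its *fitted* principal axis is exactly
# `direction` and its centroid exactly `centroid`
calibrated_helix <- function(n_res, direction, centroid, rise, radius,
                             twist, phase) {
  pts <- ideal_helix(n_res, rise, radius, twist, phase)
  ax <- fit_axis(pts)
  R <- rotation_between(ax$direction, direction / sqrt(sum(direction^2)))
  pts <- sweep(pts, 2, ax$centroid)
  pts <- pts %*% t(R)
  sweep(pts, 2, centroid, `+`)
}

#' Generate a synthetic dimer model realising a target geometry
#'
#' Builds ideal-helix C-alpha traces for both monomers so that the full
#' measurement suite ([geometry_report()]) evaluates to the spec targets
#' (angles to well under 0.5 degrees, distances to well under 0.01 nm):
#' helices are placed with self-calibrated axes, the second chain is a
#' rigid rotation of the first at the cross angle, and the measured strand
#' residues of the second chain are positioned at the exact target
#' distances. Linker and strand residues outside the measured sets are
#' interpolated. Also emits PDB text (byte-identical under the same seed).
#'
#' @param spec a [dimer_geom_spec()].
#' @param sequence 90-residue chain sequence (gapless core; default
#'   [hu_consensus_default]).
#' @param model_id identifier.
#' @param spans secondary-structure spans, see [default_ss_spans()].
#' @return list with `model` (a column-mapped [dimer_model]) and `pdb`
#'   (character scalar of PDB text).
#' @export
generate_dimer <- function(spec, sequence = hu_consensus_default,
                           model_id = "syn_dimer", spans = default_ss_spans()) {
  stopifnot(inherits(spec, "dimer_geom_spec"), nchar(sequence) == 90L)
  check_spans(spans)
  set.seed(spec$seed)
  deg <- pi / 180
  A <- matrix(NA_real_, 90, 3)

  th12 <- spec$angle_a1a2 * deg
  th23 <- spec$angle_a2a3 * deg
  thc <- spec$angle_a2a2_cross * deg
  phases <- runif(3, 0, 2 * pi)
  phi3 <- runif(1, 0, 2 * pi)

  span_len <- function(sp) sp[2] - sp[1] + 1L
  put <- function(M, sp, pts) { M[sp[1]:sp[2], ] <- pts; M }

  # helix 2 along +z at the origin
  u2 <- c(0, 0, 1)
  A <- put(A, spans$a2, calibrated_helix(span_len(spans$a2), u2, c(0, 0, 0),
                                         spec$rise, spec$radius, spec$twist,
                                         phases[1]))
  # helix 1 at the a1-a2 angle, offset to the N-terminal side
  u1 <- c(sin(th12), 0, cos(th12))
  A <- put(A, spans$a1, calibrated_helix(span_len(spans$a1), u1,
                                         c(-1.2, 0.8, -1.4),
                                         spec$rise, spec$radius, spec$twist,
                                         phases[2]))
  # helix 3 at the a2-a3 angle, offset to the C-terminal side
  u3 <- c(sin(th23) * cos(phi3), sin(th23) * sin(phi3), cos(th23))
  A <- put(A, spans$a3, calibrated_helix(span_len(spans$a3), u3,
                                         c(1.0, -1.0, 1.6),
                                         spec$rise, spec$radius, spec$twist,
                                         phases[3]))
  # beta strands: straight traces (0.34 nm rise) below the helical core
  strand <- function(sp, origin, dir) {
    dir <- dir / sqrt(sum(dir^2))
    t(sapply(seq_len(span_len(sp)) - 1L, function(k) origin + 0.34 * k * dir))
  }
  A <- put(A, spans$b1, strand(spans$b1, c(-0.8, -1.8, -0.6), c(1, 0.1, 0)))
  A <- put(A, spans$b2, strand(spans$b2, c(2.2, -2.0, -0.4), c(-1, 0.05, 0)))
  A <- put(A, spans$b3, strand(spans$b3, c(-1.4, -2.6, -0.2), c(1, 0, 0.05)))
  A <- put(A, spans$b4, strand(spans$b4, c(1.4, -2.9, 0.2), c(-1, 0, 0)))
  A <- put(A, spans$b5, strand(spans$b5, c(-1.6, -2.3, 0.6), c(1, -0.05, 0)))
  # remaining columns: linear interpolation between placed neighbours
  placed <- which(!is.na(A[, 1]))
  for (cc in which(is.na(A[, 1]))) {
    lo <- max(placed[placed < cc], -Inf)
    hi <- min(placed[placed > cc], Inf)
    if (is.infinite(lo)) {
      A[cc, ] <- A[hi, ] + (hi - cc) * c(0, 0.3, -0.3)
    } else if (is.infinite(hi)) {
      A[cc, ] <- A[lo, ] + (cc - lo) * c(0, 0.3, 0.3)
    } else {
      w <- (cc - lo) / (hi - lo)
      A[cc, ] <- (1 - w) * A[lo, ] + w * A[hi, ]
    }
  }

  # chain B: rigid rotation of A about the y axis by the cross angle,
  # then translated so the helix-2 C-termini sit at the target distance
  Rc <- rotation_between(u2, c(sin(thc), 0, cos(thc)))
  B <- A %*% t(Rc)
  h2C <- spans$a2[2]
  w_dir <- c(0.3, 0.9, 0.3); w_dir <- w_dir / sqrt(sum(w_dir^2))
  shift <- A[h2C, ] + spec$dist_h2C * w_dir - B[h2C, ]
  B <- sweep(B, 2, shift, `+`)
  # measured strand triples of chain B placed at the exact target
  # distances from their chain-A counterparts
  b2_cols <- (spans$b2[2] - 2L):spans$b2[2]
  b5_cols <- spans$b5[1]:(spans$b5[1] + 2L)
  u_b2 <- c(0, 1, 0)
  u_b5 <- c(0.2, 0.95, -0.2); u_b5 <- u_b5 / sqrt(sum(u_b5^2))
  for (t in 1:3) {
    B[b2_cols[t], ] <- A[b2_cols[t], ] + spec$dist_b2[t] * u_b2
    B[b5_cols[t], ] <- A[b5_cols[t], ] + spec$dist_b5[t] * u_b5
  }

  aa1 <- strsplit(sequence, "")[[1]]
  mk_chain <- function(M) data.frame(
    resno = 1:90, aa = aa1,
    x = M[, 1], y = M[, 2], z = M[, 3],
    column = 1:90, stringsAsFactors = FALSE)
  model <- structure(list(model_id = model_id,
                          chains = list(A = mk_chain(A), B = mk_chain(B))),
                     class = "dimer_model")
  list(model = model, pdb = write_pdb_ca(model))
}

#' Serialise a dimer model as PDB text (C-alpha trace)
#'
#' Coordinates are written in Angstrom; chains as TER-separated ATOM
#' records.
#'
#' @param model a [dimer_model].
#' @return character scalar of PDB text.
#' @export
write_pdb_ca <- function(model) {
  lines <- character(0)
  serial <- 0L
  for (ci in seq_along(model$chains)) {
    ch <- model$chains[[ci]]
    chain_id <- names(model$chains)[ci]
    for (r in seq_len(nrow(ch))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, bio3d::aa123(ch$aa[r]), chain_id, ch$resno[r],
        ch$x[r] * 10, ch$y[r] * 10, ch$z[r] * 10, 1, 0))
    }
    lines <- c(lines, "TER")
  }
  paste(c(lines, "END", ""), collapse = "\n")
}

# ---------------------------------------------------------------------------
# EMSA simulation

#' Specification for a simulated EMSA titration
#'
#' @param model a [lattice_model()] (ground truth).
#' @param dna_total DNA concentration, M (default 200 nM).
#' @param protein_totals vector of total protein concentrations, M.
#' @param noise_sd Gaussian quantification noise on band fractions
#'   (truncated at 0, rows renormalised).
#' @param seed integer seed.
#' @return object of class `emsa_sim_spec`.
#' @export
emsa_sim_spec <- function(model, dna_total = 200e-9, protein_totals,
                          noise_sd = 0.02, seed = 1L) {
  stopifnot(inherits(model, "lattice_model"), noise_sd >= 0,
            dna_total > 0, all(protein_totals > 0))
  structure(as.list(environment()), class = "emsa_sim_spec")
}

#' Simulate an EMSA titration from the lattice model
#'
#' Band fractions are the depletion-corrected occupancy probabilities plus
#' truncated Gaussian noise, renormalised per lane.
#'
#' @param spec an [emsa_sim_spec()].
#' @param dna_label structure code stored in the titration.
#' @return an [emsa_titration()].
#' @export
generate_emsa <- function(spec, dna_label = "ds") {
  stopifnot(inherits(spec, "emsa_sim_spec"))
  set.seed(spec$seed)
  fr <- predict_titration(spec$model, spec$dna_total, spec$protein_totals)
  fr <- unclass(fr)
  attr(fr, "L_free") <- NULL
  if (spec$noise_sd > 0) {
    fr <- fr + matrix(rnorm(length(fr), 0, spec$noise_sd), nrow(fr))
    fr[fr < 0] <- 0
    fr <- fr / rowSums(fr)
  }
  emsa_titration(dna_label = dna_label, dna_length = spec$model$N,
                 dna_total = spec$dna_total,
                 protein_totals = spec$protein_totals, fractions = fr)
}

#' Maximum-resolvable-complex ladder over a DNA-length series
#'
#' For each duplex length, the largest stoichiometry k whose occupancy
#' probability reaches the band detection threshold (default 5% of lane
#' signal) at the stated protein concentration.
#'
#' @param n,K,omega lattice-model parameters (site size bp, association
#'   constant 1/M, cooperativity).
#' @param lengths DNA lengths, bp (default 20:48).
#' @param dna_total,protein_total concentrations, M; the default protein
#'   concentration is strongly saturating so the fully packed state
#'   clears the detection threshold against the configurational entropy
#'   of the partially packed states.
#' @param threshold detection threshold on p_k (default 0.05).
#' @return data frame with `dna_length`, `max_complexes`.
#' @export
generate_ladder <- function(n, K, omega = 1, lengths = 20:48,
                            dna_total = 200e-9, protein_total = 2e-5,
                            threshold = 0.05) {
  counts <- vapply(lengths, function(N) {
    m <- lattice_model(n = n, K = K, omega = omega, N = N)
    L <- solve_free_ligand(m, dna_total, protein_total)
    p <- lattice_partition(m, L)$p_k
    det <- which(p >= threshold) - 1L
    if (length(det)) max(det) else 0L
  }, integer(1))
  data.frame(dna_length = lengths, max_complexes = counts)
}

#' Design a titration spanning a target occupancy range
#'
#' Chooses log-spaced total protein concentrations whose lattice
#' fractional saturation (`nu * n`, the fraction of base pairs covered)
#' runs between the requested limits under the given model, solving the
#' depletion-corrected forward model for the end points. Spanning
#' saturation rather than merely the bound-DNA fraction populates the
#' multi-ligand bands that carry the cooperativity signal.
#'
#' @param model a [lattice_model()] (ground truth).
#' @param dna_total DNA concentration, M.
#' @param n_points number of concentrations (default 8).
#' @param span fractional-saturation range (default 10-90%).
#' @return numeric vector of protein totals, M.
#' @export
design_titration <- function(model, dna_total, n_points = 8,
                             span = c(0.1, 0.9)) {
  occ_at <- function(P) {
    L <- solve_free_ligand(model, dna_total, P)
    lattice_partition(model, L)$nu * model$n
  }
  find_P <- function(target) {
    uniroot(function(p) occ_at(exp(p)) - target, log(c(1e-12, 1e-2)),
            tol = 1e-10)$root
  }
  exp(seq(find_P(span[1]), find_P(span[2]), length.out = n_points))
}
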
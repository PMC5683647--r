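#' Cooperative ligand-on-lattice binding model
#'
#' Finite-lattice McGhee-von Hippel-type model: rigid ligands (HU dimers)
#' covering `n` base pairs bind an `N`-bp lattice with intrinsic
#' association constant `K`; each pair of ligands in immediate contact
#' contributes one factor of the cooperativity `omega` (`omega < 1`
#' negative, `omega > 1` positive cooperativity).
#'
#' @param n site size in bp (>= 1).
#' @param K intrinsic association constant, 1/M.
#' @param omega cooperativity, dimensionless (> 0).
#' @param N lattice length in bp (>= n).
#' @return object of class `lattice_model`.
#' @export
lattice_model <- function(n, K, omega = 1, N) {
  stopifnot(n >= 1, N >= n, K > 0, omega > 0)
  structure(list(n = as.integer(n), K = K, omega = omega, N = as.integer(N)),
            class = "lattice_model")
}

#' Exact occupancy distribution on a finite lattice
#'
#' Equilibrium probabilities `p_k` of carrying exactly `k` ligands
#' (k = 0..floor(N/n)), from the transfer-matrix recursion over lattice
#' positions. Configuration weight is `(K * L_free)^k * omega^c` with `c`
#' the number of immediately contacting ligand pairs.
#'
#' @param model a [lattice_model()].
#' @param L_free free ligand concentration, M (>= 0).
#' @return object of class `occupancy_distribution`: `p_k` (named vector,
#'   k = 0..kmax), `mean_k`, and the binding density `nu = mean_k / N`.
#' @export
lattice_partition <- function(model, L_free) {
  stopifnot(inherits(model, "lattice_model"), L_free >= 0)
  p <- .lattice_pk_cpp(model$N, model$n, model$K * L_free, model$omega)
  k <- seq_along(p) - 1
  structure(list(p_k = setNames(p, k), mean_k = sum(k * p),
                 nu = sum(k * p) / model$N),
            class = "occupancy_distribution")
}

#' Closed-form cooperative binding density (infinite lattice)
#'
#' Solves the cooperative McGhee-von Hippel isotherm for the binding
#' density `nu` (ligands per bp) at a given free ligand concentration, by
#' bracketed root-finding on [0, 1/n).
#'
#' @param K intrinsic association constant, 1/M.
#' @param n site size, bp.
#' @param omega cooperativity (> 0).
#' @param L_free free ligand concentration, M.
#' @return binding density `nu` in [0, 1/n).
#' @export
mvh_density <- function(K, n, omega, L_free) {
  stopifnot(K > 0, n >= 1, omega > 0, L_free >= 0)
  if (L_free == 0) return(0)
  rate <- function(nu) {  # nu / L as a function of nu
    a <- 1 - n * nu
    if (a <= 0) return(0)
    if (abs(omega - 1) < 1e-9) {
      return(K * a * (a / (1 - (n - 1) * nu))^(n - 1))
    }
    R <- sqrt((1 - (n + 1) * nu)^2 + 4 * omega * nu * a)
    t1 <- ((2 * omega - 1) * a + nu - R) / (2 * (omega - 1) * a)
    t2 <- (1 - (n + 1) * nu + R) / (2 * a)
    K * a * t1^(n - 1) * t2^2
  }
  f <- function(nu) nu - L_free * rate(nu)
  hi <- 1 / n * (1 - 1e-12)
  if (f(hi) < 0) return(1 / n)  # saturation limit
  sol <- uniroot(f, c(0, hi), tol = 1e-14)
  resid <- abs(f(sol$root))
  if (resid > 1e-10 * max(1, sol$root))
    stop("isotherm root-finding failed: residual ", resid)
  sol$root
}

#' Free ligand concentration under depletion
#'
#' Solves the mass-conservation equation
#' `protein_total = L_free + dna_total * <k>(L_free)` by bisection; the
#' conservation function is strictly increasing so the root is unique.
#'
#' @param model a [lattice_model()].
#' @param dna_total,protein_total concentrations, M.
#' @return free ligand concentration in [0, protein_total], M.
#' @export
solve_free_ligand <- function(model, dna_total, protein_total) {
  stopifnot(inherits(model, "lattice_model"),
            dna_total >= 0, protein_total >= 0)
  .solve_free_cpp(model$N, model$n, model$K, model$omega,
                  dna_total, protein_total)
}

#' Depletion-corrected band fractions over a titration
#'
#' For each total protein concentration, solves for the free ligand and
#' returns the occupancy distribution row (columns k = 0..floor(N/n)).
#'
#' @param model a [lattice_model()].
#' @param dna_total DNA concentration, M.
#' @param protein_totals vector of total protein concentrations, M.
#' @return matrix with attribute `L_free`.
#' @export
predict_titration <- function(model, dna_total, protein_totals) {
  stopifnot(inherits(model, "lattice_model"))
  .titration_fractions_cpp(model$N, model$n, model$K, model$omega,
                           dna_total, as.numeric(protein_totals))
}
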
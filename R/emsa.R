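#' EMSA titration container
#'
#' Observed band fractions per complex stoichiometry over a protein
#' titration of a single DNA construct. Rows must sum to 1 within the 2%
#' quantification-noise tolerance.
#'
#' @param dna_label structure code of the construct (e.g. `"ds"`, `"J"`).
#' @param dna_length construct length, bp.
#' @param dna_total DNA concentration, M.
#' @param protein_totals vector of total protein concentrations (M, dimer
#'   units), one per row of `fractions`.
#' @param fractions matrix of band fractions; column k+1 is the fraction
#'   of DNA carrying exactly k ligands.
#' @return object of class `emsa_titration`.
#' @export
emsa_titration <- function(dna_label, dna_length, dna_total,
                           protein_totals, fractions) {
  fractions <- as.matrix(fractions)
  stopifnot(dna_length >= 1, dna_total > 0, all(protein_totals > 0),
            nrow(fractions) == length(protein_totals))
  rs <- rowSums(fractions)
  if (any(abs(rs - 1) > 0.02))
    stop("band-fraction rows must sum to 1 within 0.02")
  if (any(fractions < -1e-12)) stop("negative band fractions")
  colnames(fractions) <- seq_len(ncol(fractions)) - 1L
  structure(list(dna_label = dna_label, dna_length = as.integer(dna_length),
                 dna_total = dna_total, protein_totals = protein_totals,
                 fractions = fractions),
            class = "emsa_titration")
}

#' Write/read titration tables
#'
#' TSV with columns `dna_label`, `dna_length`, `dna_total_nM`,
#' `protein_total_nM`, `frac_k0`, `frac_k1`, ...
#'
#' @param t an [emsa_titration()].
#' @param path file path.
#' @export
write_titration <- function(t, path) {
  df <- data.frame(dna_label = t$dna_label, dna_length = t$dna_length,
                   dna_total_nM = t$dna_total * 1e9,
                   protein_total_nM = t$protein_totals * 1e9)
  fr <- t$fractions
  colnames(fr) <- paste0("frac_k", seq_len(ncol(fr)) - 1L)
  write.table(cbind(df, fr), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  df <- read.delim(path, sep = "\t")
  fr <- as.matrix(df[, grep("^frac_k", names(df)), drop = FALSE])
  emsa_titration(dna_label = df$dna_label[1], dna_length = df$dna_length[1],
                 dna_total = df$dna_total_nM[1] * 1e-9,
                 protein_totals = df$protein_total_nM * 1e-9,
                 fractions = fr)
}

#' Fit the cooperative lattice model to a titration
#'
#' Least-squares estimation of the intrinsic association constant K and
#' the cooperativity omega by matching observed band fractions to the
#' depletion-corrected finite-lattice occupancy distribution. Optimised
#' in log-parameter space (Nelder-Mead); the omega confidence interval is
#' obtained by seeded parametric bootstrap when `n_boot > 0`.
#'
#' @param t an [emsa_titration()].
#' @param n_fixed site size in bp, held fixed during the fit.
#' @param omega_fixed optionally fix omega (fit K only).
#' @param n_boot bootstrap resamples for the omega CI (default 0: no CI).
#' @param seed integer seed for the bootstrap.
#' @return object of class `binding_fit` with `Kd`, `Ka`, `omega`,
#'   `omega_ci`, `n`, `rss`, `sigma`.
#' @export
fit_cooperative <- function(t, n_fixed, omega_fixed = NULL, n_boot = 0,
                            seed = 1L) {
  stopifnot(inherits(t, "emsa_titration"))
  if (length(t$protein_totals) < 4L)
    stop("need at least 4 protein concentrations")
  bound <- 1 - t$fractions[, 1]
  if (max(bound) < 0.05)
    stop("non-identifiable: titration shows no binding")
  if (min(bound) > 0.95)
    stop("non-identifiable: titration is saturated throughout")

  obs <- t$fractions
  kmax_lat <- t$dna_length %/% n_fixed
  ncol_use <- min(ncol(obs), kmax_lat + 1L)

  predict_obs <- function(K, omega) {
    m <- lattice_model(n = n_fixed, K = K, omega = omega, N = t$dna_length)
    pr <- predict_titration(m, t$dna_total, t$protein_totals)
    out <- matrix(0, nrow(obs), ncol(obs))
    out[, seq_len(ncol_use)] <- pr[, seq_len(ncol_use)]
    # fold any unresolved higher stoichiometries into the last column
    if (ncol(pr) > ncol_use)
      out[, ncol(obs)] <- out[, ncol(obs)] +
        rowSums(pr[, (ncol_use + 1L):ncol(pr), drop = FALSE])
    out
  }
  rss_fun <- function(par) {
    K <- exp(par[1])
    omega <- if (is.null(omega_fixed)) exp(par[2]) else omega_fixed
    sum((predict_obs(K, omega) - obs)^2)
  }
  # half-saturation heuristic for the K start
  p50 <- t$protein_totals[which.min(abs(bound - 0.5))]
  if (is.null(omega_fixed)) {
    start <- c(log(1 / p50), 0)
    opt <- optim(start, rss_fun, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    opt <- optim(opt$par, rss_fun, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
  } else {
    opt <- optim(log(1 / p50), rss_fun, method = "Brent",
                 lower = log(1e2), upper = log(1e12),
                 control = list(reltol = 1e-14))
  }
  K_hat <- exp(opt$par[1])
  omega_hat <- if (is.null(omega_fixed)) exp(opt$par[2]) else omega_fixed
  n_obs <- length(obs)
  sigma <- sqrt(opt$value / n_obs)

  omega_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && is.null(omega_fixed)) {
    set.seed(seed)
    base_pred <- predict_obs(K_hat, omega_hat)
    boot <- vapply(seq_len(n_boot), function(b) {
      y <- base_pred + matrix(rnorm(n_obs, 0, sigma), nrow(base_pred))
      y[y < 0] <- 0
      y <- y / rowSums(y)
      ob <- function(par) sum((predict_obs(exp(par[1]), exp(par[2])) - y)^2)
      op <- optim(opt$par, ob, method = "Nelder-Mead",
                  control = list(maxit = 1000, reltol = 1e-10))
      exp(op$par[2])
    }, numeric(1))
    omega_ci <- unname(quantile(boot, c(0.025, 0.975)))
  }
  structure(list(Kd = 1 / K_hat, Ka = K_hat, omega = omega_hat,
                 omega_ci = omega_ci, n = n_fixed,
                 rss = opt$value, sigma = sigma,
                 convergence = opt$convergence, boot_seed = seed),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("<binding_fit> n =", x$n, "bp\n")
  cat(sprintf("  Kd = %.3g M (Ka = %.3g 1/M)\n", x$Kd, x$Ka))
  if (!is.null(x$omega))
    cat(sprintf("  omega = %.3g  [CI %.3g, %.3g]\n",
                x$omega, x$omega_ci[1], x$omega_ci[2]))
  invisible(x)
}

#' Single-site Kd with ligand depletion
#'
#' Least-squares Kd under 1:1 binding where the bound complex
#' concentration C solves `C^2 - C (P + D + Kd) + P D = 0` (smaller root)
#' and the bound fraction is `C / D`. Used for structure-specific
#' complexes quantified as a single band.
#'
#' @param protein_totals vector of total protein concentrations, M.
#' @param fraction_bound observed bound fractions (same length, within
#'   \[0, 1.02\]).
#' @param dna_total DNA concentration, M.
#' @return object of class `binding_fit` (omega absent).
#' @export
fit_kd_single_site <- function(protein_totals, fraction_bound, dna_total) {
  stopifnot(length(protein_totals) == length(fraction_bound),
            dna_total > 0)
  if (length(protein_totals) < 4L) stop("need at least 4 points")
  if (any(fraction_bound < 0 | fraction_bound > 1.02))
    stop("fractions outside [0, 1.02]")
  if (min(fraction_bound) > 0.9)
    stop("non-identifiable: only saturating data")
  pred <- function(Kd) {
    s <- protein_totals + dna_total + Kd
    C <- (s - sqrt(s^2 - 4 * protein_totals * dna_total)) / 2
    C / dna_total
  }
  obj <- function(lk) sum((pred(exp(lk)) - fraction_bound)^2)
  opt <- optimize(obj, c(log(1e-13), log(1e-2)), tol = 1e-12)
  Kd <- exp(opt$minimum)
  structure(list(Kd = Kd, Ka = 1 / Kd, omega = NULL,
                 omega_ci = c(NA_real_, NA_real_), n = NA_integer_,
                 rss = opt$objective,
                 sigma = sqrt(opt$objective / length(fraction_bound))),
            class = "binding_fit")
}

#' Binding-site size from a DNA-length ladder
#'
#' Grid search over integer site size `n` and register offset minimising
#' mismatches between observed maximum resolvable complex counts and the
#' prediction `c(N) = 1 + floor((N - offset) / n)` (clamped at 0). The
#' offset is confined to one period, 0..n: the count increments every n bp
#' and the offset fixes where in the period the steps fall. Ties are
#' broken toward smaller n, then smaller offset.
#'
#' @param ladder data frame with columns `dna_length` and `max_complexes`
#'   (at least 4 lengths, at least 2 distinct counts).
#' @param n_range candidate site sizes (default 2..20 bp).
#' @return list with `n`, `offset`, `mismatches`, and `tied_n` (all n
#'   achieving the minimal mismatch count).
#' @export
estimate_site_size <- function(ladder, n_range = 2:20) {
  stopifnot(is.data.frame(ladder),
            all(c("dna_length", "max_complexes") %in% names(ladder)))
  if (nrow(ladder) < 4L) stop("need at least 4 DNA lengths")
  if (length(unique(ladder$max_complexes)) < 2L)
    stop("non-identifiable: complex counts constant across lengths")
  N <- ladder$dna_length
  obs <- ladder$max_complexes
  best <- NULL
  results <- list()
  for (n in n_range) {
    for (off in 0:n) {
      pred <- pmax(0, 1 + floor((N - off) / n))
      mm <- sum(pred != obs)
      results[[length(results) + 1L]] <- c(n = n, offset = off,
                                           mismatches = mm)
      if (is.null(best) || mm < best["mismatches"])
        best <- c(n = n, offset = off, mismatches = mm)
    }
  }
  res <- do.call(rbind, results)
  tied <- sort(unique(res[res[, "mismatches"] == best["mismatches"], "n"]))
  list(n = as.integer(best[["n"]]), offset = as.integer(best[["offset"]]),
       mismatches = as.integer(best[["mismatches"]]),
       tied_n = as.integer(tied))
}

#' dsDNA-normalised affinity profile
#'
#' Association constants of structure-specific complexes normalised to the
#' same protein's dsDNA association constant.
#'
#' @param fits named list of [binding_fit] objects (or anything with a
#'   `Ka` field); must contain a `"ds"` entry.
#' @return data frame with `structure`, `Kd`, `Ka`, `rel_Ka` (ds row
#'   exactly 1).
#' @export
affinity_profile <- function(fits) {
  if (!"ds" %in% names(fits)) stop("missing 'ds' reference entry")
  ka <- vapply(fits, `[[`, numeric(1), "Ka")
  kd <- vapply(fits, `[[`, numeric(1), "Kd")
  data.frame(structure = names(fits), Kd = kd, Ka = ka,
             rel_Ka = ka / ka[["ds"]], row.names = NULL)
}
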
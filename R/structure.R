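#' Default secondary-structure spans on the core frame
#'
#' Core-column spans of the helices (a1, a2, a3) and beta strands
#' (b1..b5). Helix 1 spans 12 residues and helix 2 spans 21 residues by
#' default. Block boundaries are calibration data, not constants, and can
#' be overridden in every measurement function.
#'
#' @return named list of length-2 integer vectors.
#' @export
default_ss_spans <- function() {
  list(a1 = c(2L, 13L),  a2 = c(17L, 37L), a3 = c(84L, 90L),
       b1 = c(41L, 46L), b2 = c(48L, 56L), b3 = c(57L, 63L),
       b4 = c(64L, 70L), b5 = c(73L, 80L))
}

check_spans <- function(spans) {
  m <- do.call(rbind, spans)
  if (any(m[, 1] > m[, 2]) || any(m < 1L) || any(m > 90L))
    stop("spans must be ordered (start <= end) within 1..90")
  o <- order(m[, 1])
  if (any(m[o, 1][-1] <= m[o, 2][-length(spans)]))
    stop("spans must not overlap")
  invisible(spans)
}

#' Read a dimer model from PDB text or file
#'
#' Accepts a path or raw PDB text, keeps the first MODEL only, ignores
#' HETATM records (waters etc.), requires exactly two protein chains with
#' a C-alpha atom for every residue, and converts coordinates from
#' Angstrom to nm. Chains are ordered by chain identifier.
#'
#' @param pdb path to a PDB file, or a character scalar containing PDB
#'   records (detected by embedded newlines).
#' @param model_id identifier stored in the result.
#' @return object of class `dimer_model`: `model_id` and `chains`, a named
#'   list of data frames with `resno`, `aa` (one-letter), `x`, `y`, `z`
#'   (nm) and a `column` slot filled by [map_core()].
#' @export
read_model <- function(pdb, model_id = "model") {
  path <- pdb
  if (grepl("\n", pdb, fixed = TRUE)) {
    path <- tempfile(fileext = ".pdb")
    writeLines(strsplit(pdb, "\n", fixed = TRUE)[[1]], path)
    on.exit(unlink(path))
  }
  p <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- p$atom[p$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records found")
  chains <- sort(unique(at$chain))
  if (length(chains) != 2L)
    stop("expected dimer: found ", length(chains), " chain(s)")
  out <- lapply(chains, function(ch) {
    a <- at[at$chain == ch, , drop = FALSE]
    resnos <- unique(a$resno)
    ca <- a[a$elety == "CA", , drop = FALSE]
    missing <- setdiff(resnos, ca$resno)
    if (length(missing))
      stop("missing C-alpha for chain ", ch, " residues: ",
           paste(missing, collapse = ", "))
    ca <- ca[order(ca$resno), , drop = FALSE]
    data.frame(resno = ca$resno,
               aa = bio3d::aa321(ca$resid),
               x = ca$x / 10, y = ca$y / 10, z = ca$z / 10,
               column = NA_integer_,
               stringsAsFactors = FALSE)
  })
  names(out) <- chains
  structure(list(model_id = model_id, chains = out), class = "dimer_model")
}

#' Map model residues to core columns
#'
#' Labels every residue of both chains with its core column; extension and
#' inserted residues get `NA` in `column`. The chain sequence must equal
#' the raw sequence of the corresponding core-aligned record.
#'
#' @param model a [read_model()] result.
#' @param aligned a [core_aligned_seq()], or a list of two (one per chain;
#'   a single record is applied to both chains of a homodimer).
#' @return the model with per-residue `column` filled in.
#' @export
map_core <- function(model, aligned) {
  stopifnot(inherits(model, "dimer_model"))
  if (inherits(aligned, "core_aligned_seq")) aligned <- list(aligned, aligned)
  stopifnot(length(aligned) == 2L)
  for (ci in 1:2) {
    ch <- model$chains[[ci]]
    al <- aligned[[ci]]
    chain_seq <- paste(ch$aa, collapse = "")
    if (chain_seq != al$raw_seq) {
      mis <- which(strsplit(chain_seq, "")[[1]] !=
                     strsplit(al$raw_seq, "")[[1]])[1]
      stop("chain ", names(model$chains)[ci],
           " sequence mismatch at position ", mis)
    }
    cols <- rep(NA_integer_, nrow(ch))
    pos <- nchar(al$n_ext)  # residues consumed so far
    syms <- core_chars(al)
    ins_cols <- as.integer(names(al$insertions))
    for (cc in seq_len(90L)) {
      if (syms[cc] != GAP) {
        pos <- pos + 1L
        cols[pos] <- cc
      }
      hit <- which(ins_cols == cc)
      if (length(hit)) pos <- pos + nchar(al$insertions[[hit]])
    }
    model$chains[[ci]]$column <- cols
  }
  model
}

#' Fit a helix axis through C-alpha coordinates
#'
#' For a helical trace the chord second differences
#' `p[k] - 2 p[k+1] + p[k+2]` all lie in the plane perpendicular to the
#' helix axis, so the axis is the null direction of that vector set
#' (smallest right singular vector). This is exact for ideal helices of
#' any length, unlike the raw principal axis of the point cloud, which is
#' biased by the helical phase over a finite span. Near-straight spans
#' (second differences of rank < 2, e.g. beta strands) fall back to the
#' total-least-squares principal axis. The direction sign is chosen
#' toward increasing residue number (first-to-last point).
#'
#' @param coords numeric matrix (>= 5 rows, 3 columns), in residue order.
#' @return object of class `helix_axis`: unit `direction` and `centroid`.
#' @export
fit_axis <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 5L) stop("need at least 5 points to fit an axis")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  ctr <- colMeans(coords)
  X <- sweep(coords, 2, ctr)
  sv <- svd(X)
  if (sv$d[1] < 1e-8) stop("degenerate point cloud: no principal direction")
  W <- diff(coords, differences = 2L)
  svw <- svd(W)
  d <- if (svw$d[1] > 1e-10 && svw$d[2] > 1e-6 * svw$d[1]) {
    svw$v[, 3]  # curvature plane is well defined: helix
  } else {
    sv$v[, 1]   # straight or degenerate curvature: principal axis
  }
  span <- coords[nrow(coords), ] - coords[1, ]
  if (sum(d * span) < 0) d <- -d
  structure(list(direction = d / sqrt(sum(d^2)), centroid = ctr),
            class = "helix_axis")
}

#' Undirected angle between two helix axes
#'
#' `acos(|a . b|)` in degrees, in the range 0..90 regardless of axis sign.
#'
#' @param a,b [fit_axis()] results.
#' @return angle in degrees.
#' @export
interaxis_angle <- function(a, b) {
  stopifnot(inherits(a, "helix_axis"), inherits(b, "helix_axis"))
  d <- abs(sum(a$direction * b$direction))
  acos(min(1, d)) * 180 / pi
}

chain_span_coords <- function(chain, span) {
  sel <- !is.na(chain$column) & chain$column >= span[1] & chain$column <= span[2]
  as.matrix(chain[sel, c("x", "y", "z")])
}

chain_col_coord <- function(chain, col) {
  sel <- which(chain$column == col)
  if (!length(sel)) return(NULL)
  as.numeric(chain[sel[1], c("x", "y", "z")])
}

interchain_dist <- function(model, col) {
  p <- chain_col_coord(model$chains[[1]], col)
  q <- chain_col_coord(model$chains[[2]], col)
  if (is.null(p) || is.null(q)) return(NA_real_)
  sqrt(sum((p - q)^2))
}

span_axis <- function(chain, span) {
  xyz <- chain_span_coords(chain, span)
  if (nrow(xyz) < 5L) return(NULL)
  fit_axis(xyz)
}

#' Geometry measurement suite for a mapped dimer model
#'
#' Helix-axis angles within each monomer (a1-a2, a2-a3), the cross angle
#' between the two helices 2, the inter-chain C-alpha distance at the
#' C-terminal column of helix 2, and inter-chain distances at the last
#' three columns of strand b2 and the first three of strand b5 (columns
#' 54-56 and 73-75 under the default spans). A span resolving fewer than
#' 5 mapped residues yields NA for its measurements.
#'
#' @param model a column-mapped [dimer_model] (see [map_core()]).
#' @param spans secondary-structure spans, see [default_ss_spans()].
#' @return object of class `geometry_report`.
#' @export
geometry_report <- function(model, spans = default_ss_spans()) {
  stopifnot(inherits(model, "dimer_model"))
  check_spans(spans)
  if (all(is.na(model$chains[[1]]$column)))
    stop("model is not column-mapped; run map_core() first")
  ax <- lapply(model$chains, function(ch)
    list(a1 = span_axis(ch, spans$a1),
         a2 = span_axis(ch, spans$a2),
         a3 = span_axis(ch, spans$a3)))
  ang <- function(u, v) if (is.null(u) || is.null(v)) NA_real_
    else interaxis_angle(u, v)
  b2_cols <- (spans$b2[2] - 2L):spans$b2[2]
  b5_cols <- spans$b5[1]:(spans$b5[1] + 2L)
  rep <- structure(list(
    model_id = model$model_id,
    angle_a1a2 = c(ang(ax[[1]]$a1, ax[[1]]$a2), ang(ax[[2]]$a1, ax[[2]]$a2)),
    angle_a2a3 = c(ang(ax[[1]]$a2, ax[[1]]$a3), ang(ax[[2]]$a2, ax[[2]]$a3)),
    angle_a2a2_cross = ang(ax[[1]]$a2, ax[[2]]$a2),
    dist_h2C = interchain_dist(model, spans$a2[2]),
    dist_b2 = setNames(vapply(b2_cols, function(cc)
      interchain_dist(model, cc), numeric(1)), b2_cols),
    dist_b5 = setNames(vapply(b5_cols, function(cc)
      interchain_dist(model, cc), numeric(1)), b5_cols)
  ), class = "geometry_report")
  rep
}

#' @export
print.geometry_report <- function(x, ...) {
  cat("<geometry_report>", x$model_id, "\n")
  cat(sprintf("  a1-a2 angle (deg):  %.2f / %.2f\n",
              x$angle_a1a2[1], x$angle_a1a2[2]))
  cat(sprintf("  a2-a3 angle (deg):  %.2f / %.2f\n",
              x$angle_a2a3[1], x$angle_a2a3[2]))
  cat(sprintf("  a2-a2' cross (deg): %.2f\n", x$angle_a2a2_cross))
  cat(sprintf("  helix-2 C-termini distance (nm): %.3f\n", x$dist_h2C))
  cat("  b2 triple (nm):", paste(round(x$dist_b2, 3), collapse = " "), "\n")
  cat("  b5 triple (nm):", paste(round(x$dist_b5, 3), collapse = " "), "\n")
  invisible(x)
}

#' Geometry reports as a one-row-per-model table
#'
#' @param reports list of [geometry_report()] results.
#' @param path optional TSV output path.
#' @return data frame (invisibly written to `path` when given).
#' @export
geometry_table <- function(reports, path = NULL) {
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(model_id = r$model_id,
               angle_a1a2_A = r$angle_a1a2[1], angle_a1a2_B = r$angle_a1a2[2],
               angle_a2a3_A = r$angle_a2a3[1], angle_a2a3_B = r$angle_a2a3[2],
               angle_a2a2_cross = r$angle_a2a2_cross,
               dist_h2C = r$dist_h2C,
               dist_b2_1 = r$dist_b2[1], dist_b2_2 = r$dist_b2[2],
               dist_b2_3 = r$dist_b2[3],
               dist_b5_1 = r$dist_b5[1], dist_b5_2 = r$dist_b5[2],
               dist_b5_3 = r$dist_b5[3])
  }))
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Minimal C-alpha RMSD after rigid superposition
#'
#' Kabsch superposition (optimal rotation and translation, reflections
#' excluded) over the core columns mapped in both models, matched
#' chain-by-chain.
#'
#' @param a,b column-mapped [dimer_model] objects.
#' @param columns optional integer vector restricting the columns used.
#' @return RMSD in nm.
#' @export
superpose_rmsd <- function(a, b, columns = NULL) {
  P <- NULL; Q <- NULL; used <- integer(0)
  for (ci in 1:2) {
    ca <- a$chains[[ci]]; cb <- b$chains[[ci]]
    common <- intersect(ca$column[!is.na(ca$column)],
                        cb$column[!is.na(cb$column)])
    if (!is.null(columns)) common <- intersect(common, columns)
    if (length(common)) {
      P <- rbind(P, as.matrix(ca[match(common, ca$column), c("x", "y", "z")]))
      Q <- rbind(Q, as.matrix(cb[match(common, cb$column), c("x", "y", "z")]))
      used <- union(used, common)
    }
  }
  if (length(used) < 3L)
    stop("need at least 3 common mapped columns")
  kabsch_rmsd(P, Q)
}

kabsch_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Pr <- Pc %*% t(R)
  sqrt(mean(rowSums((Pr - Qc)^2)))
}
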
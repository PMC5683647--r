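#' Fitch-similarity distance matrix
#'
#' For each pair, the mean per-column Fitch (1966) similarity s over
#' columns where neither core carries a gap, transformed to
#' d = sqrt(1 - s). Identical residues are similar by construction (every
#' residue shares a class with itself), so identical cores give d = 0 and
#' pairs with no identical or similar columns give d = 1. A pair with no
#' gap-free columns has no defined similarity and is reported as NA.
#'
#' @param seqs list of at least 2 [core_aligned_seq()].
#' @return object of class `hu_dist`: list with `ids` and the symmetric
#'   `mat` of distances in 0..1 (zero diagonal).
#' @export
fitch_distance <- function(seqs) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  sim <- fitch_similarity_matrix()
  cores <- lapply(seqs, core_chars)
  n <- length(seqs)
  ids <- vapply(seqs, `[[`, character(1), "id")
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ca <- cores[[i]]; cb <- cores[[j]]
    ok <- ca != GAP & cb != GAP
    if (!any(ok)) {
      M[i, j] <- M[j, i] <- NA_real_
    } else {
      s <- mean(sim[cbind(ca[ok], cb[ok])])
      M[i, j] <- M[j, i] <- sqrt(1 - s)
    }
  }
  structure(list(ids = ids, mat = M), class = "hu_dist")
}

#' @exportS3Method base::as.matrix
as.matrix.hu_dist <- function(x, ...) x$mat

#' @export
print.hu_dist <- function(x, ...) {
  cat("<hu_dist>", length(x$ids), "sequences\n")
  print(round(x$mat, 3))
  invisible(x)
}
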
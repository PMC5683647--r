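#' Align a raw sequence onto the 90-column core frame
#'
#' Profile-to-sequence alignment: the full 90-column profile is traversed
#' (deleted columns become gaps in the core) while sequence residues may be
#' inserted between columns under affine gap penalties; residues before the
#' first and after the last aligned column are free end gaps and become the
#' N-/C-terminal extensions.
#'
#' @param raw_seq amino-acid string, length >= 30.
#' @param profile a [build_profile()] reference profile (90 columns).
#' @param gap_open,gap_extend affine gap penalties in score units
#'   (defaults 11 and 1).
#' @param id identifier for the returned record.
#' @return a [core_aligned_seq()] with an extra attribute `score`.
#' @export
align_to_core <- function(raw_seq, profile, gap_open = 11, gap_extend = 1,
                          id = "query") {
  stopifnot(is.character(raw_seq), length(raw_seq) == 1L)
  raw_seq <- toupper(raw_seq)
  m <- nchar(raw_seq)
  if (m < 30L) stop("sequence shorter than 30 residues")
  a <- strsplit(raw_seq, "")[[1]]
  ai <- match(a, AA_ALPHABET)
  if (anyNA(ai))
    stop("non-standard residues at positions ",
         paste(which(is.na(ai)), collapse = ", "))
  S <- profile$score
  if (!all(is.finite(S[, 1:20]))) stop("profile has non-finite column scores")

  nc <- 90L
  NEG <- -1e15
  # rows index profile columns 0..90; cols index sequence prefixes 0..m
  M <- matrix(NEG, nc + 1L, m + 1L)
  I <- matrix(NEG, nc + 1L, m + 1L)
  D <- matrix(NEG, nc + 1L, m + 1L)
  PM <- matrix(0L, nc + 1L, m + 1L)
  PI <- matrix(0L, nc + 1L, m + 1L)
  PD <- matrix(0L, nc + 1L, m + 1L)
  M[1L, ] <- 0  # free sequence prefix before the first aligned column

  for (i in 2:(nc + 1L)) {
    ic <- i - 1L
    # deletion of column ic (no residue consumed), incl. j = 0
    dc <- cbind(M[i - 1L, ] - gap_open, D[i - 1L, ] - gap_extend)
    pd <- max.col(dc, ties.method = "first")
    D[i, ] <- dc[cbind(seq_len(m + 1L), pd)]
    PD[i, ] <- c(1L, 3L)[pd]
    # match column ic with residue j
    mc <- cbind(M[i - 1L, 1:m], I[i - 1L, 1:m], D[i - 1L, 1:m])
    pm <- max.col(mc, ties.method = "first")
    M[i, 2:(m + 1L)] <- S[ic, ai] + mc[cbind(seq_len(m), pm)]
    PM[i, 2:(m + 1L)] <- pm
    # insertions after column ic (keys restricted to 1..89)
    if (ic <= 89L) {
      for (j in 2:(m + 1L)) {
        o <- M[i, j - 1L] - gap_open
        e <- I[i, j - 1L] - gap_extend
        if (o >= e) { I[i, j] <- o; PI[i, j] <- 1L }
        else        { I[i, j] <- e; PI[i, j] <- 2L }
      }
    }
  }

  # free sequence suffix: end in M or D at row 90, any j
  endM <- max(M[nc + 1L, ])
  endD <- max(D[nc + 1L, ])
  if (endM >= endD) {
    state <- 1L; j <- which.max(M[nc + 1L, ])
  } else {
    state <- 3L; j <- which.max(D[nc + 1L, ])
  }
  best_score <- max(endM, endD)
  if (!is.finite(best_score) || best_score <= NEG / 2)
    stop("no finite alignment found")

  core <- character(nc)
  insertions <- list()
  i <- nc + 1L
  j_end <- j - 1L  # last consumed residue index
  while (i > 1L) {
    ic <- i - 1L
    if (state == 1L) {            # match
      core[ic] <- a[j - 1L]
      state <- PM[i, j]
      i <- i - 1L; j <- j - 1L
    } else if (state == 3L) {     # deletion
      core[ic] <- GAP
      state <- PD[i, j]
      i <- i - 1L
    } else {                      # insertion after column ic
      key <- as.character(ic)
      insertions[[key]] <- paste0(a[j - 1L],
                                  if (key %in% names(insertions))
                                    insertions[[key]] else "")
      state <- PI[i, j]
      j <- j - 1L
    }
  }
  j_start <- j - 1L  # residues 1..j_start form the N-terminal extension

  core_aligned_seq(
    id = id,
    core = paste(core, collapse = ""),
    insertions = insertions,
    n_ext = substr(raw_seq, 1L, j_start),
    c_ext = substr(raw_seq, j_end + 1L, m)
  ) -> out
  attr(out, "score") <- best_score
  out
}
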
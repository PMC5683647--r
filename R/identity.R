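#' Core identity count between two aligned sequences
#'
#' Number of identical positions in the 90-column core under event-based
#' indel accounting: a column where both sequences carry the same residue
#' (or both a gap) is identical; a column with two different residues is
#' one non-identity; a maximal run of columns gapped in one sequence but
#' not the other counts as a single deletion event (one non-identity,
#' regardless of run length); an insertion present in only one sequence,
#' or differing between the two, counts as one non-identity per event.
#' The count is floored at 0.
#'
#' @param a,b [core_aligned_seq()] objects.
#' @return integer in 0..90; symmetric in its arguments.
#' @export
core_identity <- function(a, b) {
  stopifnot(inherits(a, "core_aligned_seq"), inherits(b, "core_aligned_seq"))
  ca <- core_chars(a)
  cb <- core_chars(b)
  both_res <- ca != GAP & cb != GAP
  mismatches <- sum(both_res & ca != cb)
  # deletion events: maximal runs where exactly one core is gapped
  one_gap <- xor(ca == GAP, cb == GAP)
  r <- rle(one_gap)
  del_events <- sum(r$values)
  # insertion events: columns where the inserted runs differ
  cols <- union(names(a$insertions), names(b$insertions))
  ins_events <- sum(vapply(cols, function(k) {
    ia <- if (k %in% names(a$insertions)) a$insertions[[k]] else ""
    ib <- if (k %in% names(b$insertions)) b$insertions[[k]] else ""
    ia != ib
  }, logical(1)))
  max(0L, 90L - mismatches - del_events - ins_events)
}

#' Pairwise core-identity matrix
#'
#' @param seqs list of [core_aligned_seq()].
#' @return symmetric integer matrix with sequence ids as dimnames.
#' @export
core_identity_matrix <- function(seqs) {
  n <- length(seqs)
  ids <- vapply(seqs, `[[`, character(1), "id")
  M <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    M[i, i] <- core_identity(seqs[[i]], seqs[[i]])
    if (i < n) for (j in (i + 1):n) {
      M[i, j] <- M[j, i] <- core_identity(seqs[[i]], seqs[[j]])
    }
  }
  M
}
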
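#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard residues in alphabetical one-letter order. Core columns
#' may additionally carry the gap symbol `"-"`.
#'
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP <- "-"

# Fitch (1966) residue-similarity classes: two residues score 1 when they
# fall in the same class and 0 otherwise. This replicates the protein
# similarity matrix used by seqinr::dist.alignment(matrix = "similarity").
FITCH_CLASSES <- list(
  c("A", "G"),
  c("R", "N", "D", "Q", "E", "H", "K", "S", "T"),
  c("C", "I", "L", "M", "F", "W", "Y", "V"),
  c("P")
)

#' Fitch residue-similarity matrix
#'
#' Binary 20 x 20 similarity table derived from the Fitch (1966)
#' classification of amino acids: 1 within a class, 0 across classes.
#' Used by [fitch_distance()].
#'
#' @return numeric matrix with residue one-letter row/column names.
#' @export
fitch_similarity_matrix <- function() {
  S <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (cls in FITCH_CLASSES) S[cls, cls] <- 1
  S
}

#' Default HU-like 90-residue core consensus
#'
#' A synthetic consensus for the 90-column HU/IHF core frame, used as the
#' default seed sequence by the family generator. It mimics the residue
#' composition and architecture (two N-terminal helices, beta-saddle,
#' C-terminal helix) of bacterial HU cores but is not the sequence of any
#' particular organism.
#'
#' @export
hu_consensus_default <- paste0(
  "MNKSELIDKV", "AEKAGLTKKD", "ATKAVDAVFD", "SITEALRKGD",
  "KVQLIGFGNF", "EVRERAARKG", "RNPQTGEEIE", "IPASKVPAFK", "PGKALKDAVK"
)
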
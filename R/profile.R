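#' Build a position-specific score matrix for a clade
#'
#' Column residue frequencies with an additive pseudocount, log-odds scores
#' against a uniform residue background, the modal-residue consensus and
#' the per-column conservation (fraction of members matching the
#' consensus). Score units are bits (log2 odds).
#'
#' @param members list of [core_aligned_seq()] (at least 2).
#' @param pseudocount additive pseudocount per residue (default 0.5).
#' @param name profile name (clade label).
#' @param group optional group annotation (`"HU"`, `"IHF_A"`, `"IHF_B"`).
#' @param gap_background assumed background gap rate for the gap log-odds
#'   column (default 0.05).
#'
#' @return object of class `clade_profile` with fields `name`, `group`,
#'   `n_members`, `freq` (90 x 20), `score` (90 x 21; 21st column is the
#'   gap score), `consensus` (90-character string), `conservation`.
#' @export
build_profile <- function(members, pseudocount = 0.5, name = "profile",
                          group = NA_character_, gap_background = 0.05) {
  if (length(members) < 2L) stop("need at least 2 members")
  stopifnot(all(vapply(members, inherits, logical(1), "core_aligned_seq")))
  M <- do.call(rbind, lapply(members, core_chars))
  if (ncol(M) != 90L) stop("members with unequal core length")
  n <- nrow(M)
  freq <- matrix(0, 90, 20, dimnames = list(NULL, AA_ALPHABET))
  score <- matrix(0, 90, 21, dimnames = list(NULL, c(AA_ALPHABET, GAP)))
  consensus <- character(90)
  conservation <- numeric(90)
  for (cc in seq_len(90L)) {
    col <- M[, cc]
    res <- col[col != GAP]
    cnt <- table(factor(res, levels = AA_ALPHABET))
    freq[cc, ] <- (as.numeric(cnt) + pseudocount) /
      (length(res) + 20 * pseudocount)
    score[cc, 1:20] <- log2(freq[cc, ] * 20)
    gap_rate <- (sum(col == GAP) + pseudocount) / (n + 2 * pseudocount)
    score[cc, 21] <- log2(gap_rate / gap_background)
    if (length(res)) {
      mx <- max(cnt)
      consensus[cc] <- sort(names(cnt)[cnt == mx])[1]  # tie: lexicographic
    } else {
      consensus[cc] <- GAP
    }
    conservation[cc] <- mean(col == consensus[cc])
  }
  structure(
    list(name = name, group = group, n_members = n, freq = freq,
         score = score, consensus = paste(consensus, collapse = ""),
         conservation = conservation, pseudocount = pseudocount),
    class = "clade_profile")
}

#' Score an aligned core against a profile
#'
#' Sum of per-column log-odds scores (gap columns use the profile's gap
#' score) minus an affine penalty per insertion event
#' (`gap_open + gap_extend * (len - 1)`).
#'
#' @param s a [core_aligned_seq()].
#' @param profile a [build_profile()] result.
#' @param gap_open,gap_extend affine insertion penalties in score units.
#' @return numeric scalar.
#' @export
score_core <- function(s, profile, gap_open = 11, gap_extend = 1) {
  syms <- core_chars(s)
  idx <- match(syms, c(AA_ALPHABET, GAP))
  total <- sum(profile$score[cbind(seq_len(90L), idx)])
  if (length(s$insertions)) {
    lens <- nchar(unlist(s$insertions))
    total <- total - sum(gap_open + gap_extend * (lens - 1))
  }
  total
}

#' Assign a sequence to a group and clade by profile score
#'
#' The best-scoring profile wins; the margin is the score difference to the
#' runner-up. Assignments with a margin below `margin_threshold` are
#' flagged ambiguous (ties included).
#'
#' @param s a [core_aligned_seq()].
#' @param profiles list of [build_profile()] results covering the groups.
#' @param margin_threshold ambiguity margin in score units (default 5).
#' @return list with `group`, `clade`, `margin`, `ambiguous`, and the full
#'   named `scores` vector.
#' @export
classify_sequence <- function(s, profiles, margin_threshold = 5) {
  if (!length(profiles)) stop("empty profile list")
  scores <- vapply(profiles, function(p) score_core(s, p), numeric(1))
  names(scores) <- vapply(profiles, `[[`, character(1), "name")
  ord <- order(scores, decreasing = TRUE)
  best <- profiles[[ord[1]]]
  margin <- if (length(scores) > 1L)
    unname(scores[ord[1]] - scores[ord[2]]) else Inf
  list(group = best$group, clade = best$name,
       margin = margin,
       ambiguous = margin < margin_threshold,
       scores = scores)
}
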
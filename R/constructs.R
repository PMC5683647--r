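#' Oligonucleotide
#'
#' @param name oligo name.
#' @param sequence 5'->3' DNA sequence (ACGT only, length >= 8).
#' @param labeled logical; carries the 5'-HEX fluorescent label.
#' @return object of class `oligo`.
#' @export
oligo <- function(name, sequence, labeled = FALSE) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 8L) stop("oligo must be at least 8 nt")
  if (grepl("[^ACGT]", sequence)) stop("oligo alphabet is ACGT only")
  structure(list(name = name, sequence = sequence, labeled = labeled),
            class = "oligo")
}

#' Reverse complement of a DNA string
#'
#' @param s DNA string (ACGT).
#' @return character scalar.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' The D-48 duplex template strand
#'
#' The 48-nt labeled oligonucleotide from which the duplex truncation
#' series and the branched constructs are derived.
#'
#' @return an [oligo()].
#' @export
oligo_d48 <- function() {
  oligo("D-48",
        "AGTCTAGAGTGCAGTTGAGTCCTTGCTACGACGGATCCCTTAGGTCAG",
        labeled = TRUE)
}

#' Anneal oligonucleotides into an assembly
#'
#' Greedy maximal pairing: repeatedly adds the longest exact antiparallel
#' reverse-complement match of at least `min_match` bp between unpaired
#' regions of two different strands, until none remains. Strands are
#' canonicalised (labeled first, then by name and sequence) before the
#' greedy loop, so the result is independent of input order; remaining
#' ties go to the earliest position on the first (labeled) strand.
#' Thermodynamics is not modelled: the constructs are designed for unique
#' exact pairing.
#'
#' @param oligos list of 1-4 [oligo()] objects.
#' @param min_match minimum duplex segment length, bp (default 8).
#' @return object of class `assembly`: `strands` (data frame), `pairing`
#'   (per-strand lists of partner strand/base per position, 0 = unpaired)
#'   and `segments` (one row per duplex segment).
#' @export
anneal <- function(oligos, min_match = 8L) {
  if (inherits(oligos, "oligo")) oligos <- list(oligos)
  stopifnot(length(oligos) >= 1L, length(oligos) <= 4L,
            all(vapply(oligos, inherits, logical(1), "oligo")))
  ord <- order(!vapply(oligos, `[[`, logical(1), "labeled"),
               vapply(oligos, `[[`, character(1), "name"),
               vapply(oligos, `[[`, character(1), "sequence"))
  oligos <- oligos[ord]
  ns <- length(oligos)
  seqs <- lapply(oligos, function(o) strsplit(o$sequence, "")[[1]])
  lens <- lengths(seqs)
  partner_strand <- lapply(lens, function(l) integer(l))
  partner_base <- lapply(lens, function(l) integer(l))
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  find_best <- function() {
    best <- NULL
    for (i in seq_len(ns)) for (j in seq_len(ns)) {
      if (i == j) next
      si <- seqs[[i]]; sj <- seqs[[j]]
      # longest run where si[a + t] pairs sj[b - t] (antiparallel WC),
      # all positions unpaired in both strands
      L <- matrix(0L, lens[i] + 1L, lens[j] + 2L)
      for (a in seq_len(lens[i])) {
        for (b in seq_len(lens[j])) {
          ok <- partner_strand[[i]][a] == 0L && partner_strand[[j]][b] == 0L &&
            si[a] == comp[[sj[b]]]
          L[a + 1L, b + 1L] <- if (ok) L[a, b + 2L] + 1L else 0L
        }
      }
      for (a in seq_len(lens[i])) for (b in seq_len(lens[j])) {
        len <- L[a + 1L, b + 1L]
        if (len >= min_match) {
          cand <- list(i = i, j = j, a_end = a, b_start = b, len = len)
          if (is.null(best) ||
              len > best$len ||
              (len == best$len &&
               (i < best$i || (i == best$i &&
                (a - len + 1L) < (best$a_end - best$len + 1L))))) {
            best <- cand
          }
        }
      }
    }
    best
  }

  any_pairing <- FALSE
  segments <- list()
  repeat {
    best <- find_best()
    if (is.null(best)) break
    any_pairing <- TRUE
    a0 <- best$a_end - best$len + 1L
    for (tt in 0:(best$len - 1L)) {
      ai <- a0 + tt
      bj <- best$b_start + best$len - 1L - tt
      partner_strand[[best$i]][ai] <- best$j
      partner_base[[best$i]][ai] <- bj
      partner_strand[[best$j]][bj] <- best$i
      partner_base[[best$j]][bj] <- ai
    }
    segments[[length(segments) + 1L]] <- data.frame(
      strand = best$i, start = a0, end = best$a_end,
      partner = best$j, partner_start = best$b_start + best$len - 1L,
      partner_end = best$b_start, length = best$len)
  }
  if (ns >= 2L && !any_pairing) stop("no stable assembly")

  # drop mirror duplicates (each segment found once per orientation choice)
  seg <- if (length(segments)) do.call(rbind, segments) else
    data.frame(strand = integer(0), start = integer(0), end = integer(0),
               partner = integer(0), partner_start = integer(0),
               partner_end = integer(0), length = integer(0))
  structure(list(
    strands = data.frame(
      name = vapply(oligos, `[[`, character(1), "name"),
      sequence = vapply(oligos, `[[`, character(1), "sequence"),
      labeled = vapply(oligos, `[[`, logical(1), "labeled"),
      stringsAsFactors = FALSE),
    pairing = list(strand = partner_strand, base = partner_base),
    segments = seg
  ), class = "assembly")
}

unpaired_runs <- function(a, strand_idx) {
  ps <- a$pairing$strand[[strand_idx]]
  r <- rle(ps == 0L)
  if (!any(r$values)) return(data.frame(start = integer(0), end = integer(0),
                                        terminal = logical(0)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             terminal = starts[keep] == 1L | ends[keep] == length(ps))
}

#' Classify an annealed assembly into the structure categories
#'
#' Rule-based topology labels: `ds` full duplex; `n` nicked duplex (three
#' strands, no unpaired bases); `A1`/`A3`/`A7` duplex with an internal
#' 1/3/7-nt unpaired run on one strand (bulge); `ov` duplex with a single
#' terminal single-stranded tail; `fork` two tails at the same duplex end;
#' `J` four strands forming a four-way junction (pairing graph a 4-cycle,
#' all bases paired); `iJ` three-strand junction lacking one strand (two
#' terminal tails on different strands); `inv` strand invasion (three
#' strands, central strand fully paired to both partners, one terminal
#' tail). Anything else is `unknown`.
#'
#' @param a an [anneal()] result.
#' @return character label.
#' @export
classify_structure <- function(a) {
  stopifnot(inherits(a, "assembly"))
  ns <- nrow(a$strands)
  runs <- lapply(seq_len(ns), function(i) unpaired_runs(a, i))
  n_unpaired <- sum(vapply(runs, function(r)
    sum(r$end - r$start + 1L), integer(1)))
  internal <- do.call(rbind, lapply(seq_len(ns), function(i) {
    r <- runs[[i]][!runs[[i]]$terminal, , drop = FALSE]
    if (nrow(r)) cbind(strand = i, r) else NULL
  }))
  terminal <- do.call(rbind, lapply(seq_len(ns), function(i) {
    r <- runs[[i]][runs[[i]]$terminal, , drop = FALSE]
    if (nrow(r)) cbind(strand = i, r) else NULL
  }))
  n_internal <- if (is.null(internal)) 0L else nrow(internal)
  n_terminal <- if (is.null(terminal)) 0L else nrow(terminal)
  partners_of <- function(i)
    sort(unique(a$pairing$strand[[i]][a$pairing$strand[[i]] != 0L]))

  if (ns == 2L) {
    if (n_unpaired == 0L) return("ds")
    if (n_internal == 1L && n_terminal == 0L) {
      m <- internal$end[1] - internal$start[1] + 1L
      return(if (m %in% c(1L, 3L, 7L)) paste0("A", m) else "unknown")
    }
    if (n_internal == 0L && n_terminal == 1L) return("ov")
    if (n_internal == 0L && n_terminal == 2L &&
        length(unique(terminal$strand)) == 2L) {
      # same duplex end: one tail 5'-terminal on one strand, the other
      # 3'-terminal on the other strand
      side <- function(k) {
        if (terminal$start[k] == 1L) "5p" else "3p"
      }
      if (side(1) != side(2)) return("fork")
    }
    return("unknown")
  }
  if (ns == 3L) {
    deg <- vapply(seq_len(ns), function(i) length(partners_of(i)), integer(1))
    if (!any(deg == 2L)) return("unknown")
    if (n_internal > 0L) return("unknown")
    if (n_terminal == 0L) return("n")
    if (n_terminal == 1L) return("inv")
    if (n_terminal == 2L && length(unique(terminal$strand)) == 2L)
      return("iJ")
    return("unknown")
  }
  if (ns == 4L) {
    deg <- vapply(seq_len(ns), function(i) length(partners_of(i)), integer(1))
    if (n_unpaired == 0L && all(deg == 2L)) return("J")
    return("unknown")
  }
  "unknown"
}

#' 3'-truncation duplex series
#'
#' For each requested length L, anneals the 5' L-nt prefix of the template
#' with its exact reverse complement, as used for the binding-site-size
#' ladder substrates.
#'
#' @param template an [oligo()] (e.g. [oligo_d48()]).
#' @param lengths integer vector of duplex lengths (8 <= L <= template
#'   length).
#' @return named list of duplex [anneal()] assemblies.
#' @export
truncation_series <- function(template, lengths) {
  stopifnot(inherits(template, "oligo"))
  if (any(lengths > nchar(template$sequence)))
    stop("lengths exceed the template")
  if (any(lengths < 8L)) stop("lengths below 8 nt cannot form stable duplexes")
  out <- lapply(lengths, function(L) {
    top <- oligo(sprintf("%s-%d", template$name, L),
                 substr(template$sequence, 1L, L), labeled = template$labeled)
    bot <- oligo(sprintf("%s-%d.c", template$name, L),
                 revcomp(top$sequence))
    anneal(list(top, bot))
  })
  names(out) <- sprintf("%s-%d", template$name, lengths)
  out
}
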
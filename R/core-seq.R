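#' Core-aligned HU/IHF sequence
#'
#' Represents a family member decomposed on the 90-column conserved core
#' frame: the core itself (with `-` for deleted columns), insertions keyed
#' by the core column they follow, and the N-/C-terminal extensions that
#' fall outside the frame.
#'
#' @param id sequence identifier.
#' @param core character scalar of exactly 90 symbols (residues or `-`).
#' @param insertions named list/character vector; names are core columns
#'   (1-89), values the residue run inserted between that column and the
#'   next.
#' @param n_ext,c_ext terminal extension strings (possibly empty).
#' @param organism,taxonomy,group,clade optional annotations; `group` must
#'   be one of `"HU"`, `"IHF_A"`, `"IHF_B"` when set.
#' @param raw_seq full-length sequence; reconstructed from the parts when
#'   `NULL`, otherwise checked against the reconstruction.
#'
#' @return an object of class `core_aligned_seq`.
#' @export
core_aligned_seq <- function(id, core, insertions = list(), n_ext = "",
                             c_ext = "", organism = NA_character_,
                             taxonomy = character(), group = NA_character_,
                             clade = NA_character_, raw_seq = NULL) {
  stopifnot(is.character(core), length(core) == 1L)
  if (nchar(core) != 90L)
    stop("core must be exactly 90 symbols, got ", nchar(core))
  syms <- strsplit(core, "")[[1]]
  bad <- setdiff(unique(syms), c(AA_ALPHABET, GAP))
  if (length(bad))
    stop("core contains invalid symbols: ", paste(bad, collapse = ", "))
  insertions <- as.list(insertions)
  if (length(insertions)) {
    cols <- suppressWarnings(as.integer(names(insertions)))
    if (anyNA(cols) || any(cols < 1L) || any(cols > 89L))
      stop("insertion keys must be core columns in 1..89")
    if (anyDuplicated(cols)) stop("duplicated insertion columns")
    insertions <- insertions[order(cols)]
    if (any(!nzchar(unlist(insertions))))
      stop("insertions must be non-empty residue strings")
  }
  x <- structure(
    list(id = id, organism = organism, taxonomy = taxonomy,
         core = core, insertions = insertions,
         n_ext = n_ext, c_ext = c_ext,
         group = group, clade = clade, raw_seq = NULL),
    class = "core_aligned_seq")
  rec <- reconstruct_raw(x)
  if (!is.null(raw_seq) && raw_seq != rec)
    stop("raw_seq does not match reconstruction from core/insertions/extensions")
  x$raw_seq <- rec
  if (!is.na(group) && !group %in% c("HU", "IHF_A", "IHF_B"))
    stop("group must be HU, IHF_A or IHF_B")
  x
}

#' Rebuild the full-length sequence of a core-aligned record
#'
#' Concatenates the N-terminal extension, the gap-free core with insertions
#' spliced back between their columns, and the C-terminal extension.
#'
#' @param x a [core_aligned_seq()].
#' @return character scalar.
#' @export
reconstruct_raw <- function(x) {
  stopifnot(inherits(x, "core_aligned_seq"))
  syms <- strsplit(x$core, "")[[1]]
  ins_cols <- as.integer(names(x$insertions))
  parts <- character(0)
  for (cc in seq_len(90L)) {
    if (syms[cc] != GAP) parts <- c(parts, syms[cc])
    hit <- which(ins_cols == cc)
    if (length(hit)) parts <- c(parts, x$insertions[[hit]])
  }
  paste0(x$n_ext, paste(parts, collapse = ""), x$c_ext)
}

core_chars <- function(x) strsplit(x$core, "")[[1]]

#' @export
print.core_aligned_seq <- function(x, ...) {
  cat("<core_aligned_seq>", x$id, "\n")
  cat("  core:", x$core, "\n")
  if (length(x$insertions))
    cat("  insertions:",
        paste(sprintf("%s:%s", names(x$insertions), unlist(x$insertions)),
              collapse = "; "), "\n")
  if (nzchar(x$n_ext)) cat("  n_ext:", x$n_ext, "\n")
  if (nzchar(x$c_ext)) cat("  c_ext:", x$c_ext, "\n")
  if (!is.na(x$group)) cat("  group:", x$group, " clade:", x$clade, "\n")
  invisible(x)
}
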
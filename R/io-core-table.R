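#' Read and write the aligned-core table
#'
#' Tab-separated exchange format for core-aligned sequences: columns
#' `id`, `organism`, `taxonomy` (ranks joined by `;`), `n_ext`, `core`
#' (90 characters including `-`), `insertions` (`col:res` pairs joined by
#' `;`), `c_ext`, `group`, `clade`.
#'
#' @param seqs list of [core_aligned_seq()].
#' @param path file path.
#' @return `read_core_table` returns a list of [core_aligned_seq()];
#'   `write_core_table` returns `path` invisibly.
#' @export
write_core_table <- function(seqs, path) {
  rows <- lapply(seqs, function(s) {
    data.frame(
      id = s$id,
      organism = ifelse(is.na(s$organism), "", s$organism),
      taxonomy = paste(s$taxonomy, collapse = ";"),
      n_ext = s$n_ext,
      core = s$core,
      insertions = if (length(s$insertions))
        paste(sprintf("%s:%s", names(s$insertions), unlist(s$insertions)),
              collapse = ";") else "",
      c_ext = s$c_ext,
      group = ifelse(is.na(s$group), "", s$group),
      clade = ifelse(is.na(s$clade), "", s$clade),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_core_table
#' @export
read_core_table <- function(path) {
  df <- read.delim(path, sep = "\t", colClasses = "character")
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    ins <- list()
    if (nzchar(r$insertions)) {
      parts <- strsplit(r$insertions, ";", fixed = TRUE)[[1]]
      kv <- strsplit(parts, ":", fixed = TRUE)
      ins <- setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, character(1), 1))
    }
    core_aligned_seq(
      id = r$id,
      organism = if (nzchar(r$organism)) r$organism else NA_character_,
      taxonomy = if (nzchar(r$taxonomy))
        strsplit(r$taxonomy, ";", fixed = TRUE)[[1]] else character(0),
      core = r$core, insertions = ins,
      n_ext = r$n_ext, c_ext = r$c_ext,
      group = if (nzchar(r$group)) r$group else NA_character_,
      clade = if (nzchar(r$clade)) r$clade else NA_character_)
  })
}

#' FASTA input/output for protein sequences
#'
#' Thin wrappers over Biostrings keeping identifiers verbatim; sequences
#' are returned as a named character vector and written wrapped at 60
#' columns.
#'
#' @param path file path.
#' @param seqs named character vector of amino-acid sequences.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
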
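#' Default indel hotspot regions of the core frame
#'
#' Core-column spans for the loop between helices 1 and 2, the turn
#' between helix 2 and strand 1, and the DNA-interacting arm tip.
#' Remaining columns form the implicit "other" region. The spans are
#' calibration data and can be overridden.
#'
#' @return named list of length-2 integer vectors (start, end).
#' @export
default_indel_regions <- function() {
  list(loop_a1_a2 = c(14L, 16L),
       turn_a2_b1 = c(38L, 40L),
       arm_tip    = c(60L, 68L))
}

check_regions <- function(regions) {
  for (r in regions) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1L || r[2] > 90L)
      stop("region spans must be (start, end) within 1..90")
  }
  cols <- unlist(lapply(regions, function(r) r[1]:r[2]))
  if (anyDuplicated(cols)) stop("overlapping regions")
  invisible(regions)
}

region_of_column <- function(col, regions) {
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (col >= r[1] && col <= r[2]) return(nm)
  }
  "other"
}

#' Census of insertion and deletion events across an alignment
#'
#' Events are counted per contiguous run (one insertion event per inserted
#' run regardless of its length; one deletion event per maximal gap run)
#' and assigned to the hotspot region containing the event's start column.
#'
#' @param seqs list of [core_aligned_seq()].
#' @param regions named region spans as in [default_indel_regions()].
#' @return object of class `indel_census`: per-region table with event
#'   counts, per-sequence rates, and the fraction of all insertion events
#'   falling in each region; plus the overall single-residue insert
#'   fraction and insert-length histograms.
#' @export
indel_census <- function(seqs, regions = default_indel_regions()) {
  check_regions(regions)
  region_names <- c(names(regions), "other")
  n <- length(seqs)
  ins_events <- del_events <- setNames(numeric(length(region_names)),
                                       region_names)
  ins_seqs <- del_seqs <- setNames(numeric(length(region_names)),
                                   region_names)
  ins_lengths <- list()
  for (s in seqs) {
    ins_cols <- as.integer(names(s$insertions))
    ins_regs <- vapply(ins_cols, region_of_column, character(1),
                       regions = regions)
    for (rg in region_names) ins_events[rg] <- ins_events[rg] + sum(ins_regs == rg)
    for (rg in unique(ins_regs)) ins_seqs[rg] <- ins_seqs[rg] + 1
    ins_lengths <- c(ins_lengths,
                     Map(function(rg, len) c(region = rg, len = len),
                         ins_regs, nchar(unlist(s$insertions))))
    gaps <- core_chars(s) == GAP
    r <- rle(gaps)
    if (any(r$values)) {
      starts <- cumsum(c(1L, r$lengths))[seq_along(r$values)][r$values]
      del_regs <- vapply(starts, region_of_column, character(1),
                         regions = regions)
      for (rg in region_names) del_events[rg] <- del_events[rg] + sum(del_regs == rg)
      for (rg in unique(del_regs)) del_seqs[rg] <- del_seqs[rg] + 1
    }
  }
  total_ins <- sum(ins_events)
  all_lens <- if (length(ins_lengths))
    as.integer(vapply(ins_lengths, `[[`, character(1), "len")) else integer(0)
  tab <- data.frame(
    region = region_names,
    insert_events = as.integer(ins_events),
    insert_rate = ins_seqs / n,
    insert_fraction = if (total_ins > 0) ins_events / total_ins else
      rep(NA_real_, length(region_names)),
    delete_events = as.integer(del_events),
    delete_rate = del_seqs / n,
    row.names = NULL)
  structure(list(
    table = tab,
    n_sequences = n,
    total_insert_events = total_ins,
    single_residue_fraction = if (length(all_lens)) mean(all_lens == 1L)
      else NA_real_,
    insert_length_hist = if (length(all_lens)) table(all_lens) else table(integer(0))
  ), class = "indel_census")
}

#' @export
print.indel_census <- function(x, ...) {
  cat("<indel_census> over", x$n_sequences, "sequences;",
      x$total_insert_events, "insertion events\n")
  print(x$table, digits = 3)
  cat("single-residue insert fraction:",
      round(x$single_residue_fraction, 3), "\n")
  invisible(x)
}

#' Composition statistics of a terminal extension
#'
#' Length, counts of the charged residues K/R/D/E, and all (possibly
#' overlapping) occurrences of the lysine-rich "PAKKA" repeat motif.
#'
#' @param s a [core_aligned_seq()].
#' @param side `"N"` or `"C"`.
#' @return object of class `terminal_stats` with fields `side`, `length`,
#'   `count_K`, `count_R`, `count_D`, `count_E`, `pakka_hits` (1-based
#'   start offsets within the extension).
#' @export
terminal_stats <- function(s, side = c("N", "C")) {
  side <- match.arg(side)
  ext <- if (side == "N") s$n_ext else s$c_ext
  chars <- if (nzchar(ext)) strsplit(ext, "")[[1]] else character(0)
  hits <- integer(0)
  if (nchar(ext) >= 5L) {
    g <- gregexpr("(?=PAKKA)", ext, perl = TRUE)[[1]]
    if (g[1] != -1L) hits <- as.integer(g)
  }
  structure(list(side = side, length = length(chars),
                 count_K = sum(chars == "K"), count_R = sum(chars == "R"),
                 count_D = sum(chars == "D"), count_E = sum(chars == "E"),
                 pakka_hits = hits),
            class = "terminal_stats")
}
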
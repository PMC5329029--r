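#' Median position of a peptide across sequences
#'
#' The position of a conserved peptide is defined as the median, over all
#' sequences containing it, of the 1-based start of its first occurrence.
#' The median (middle value for an odd count, mean of the two middle values
#' for an even count, so possibly half-integer) is robust to the length
#' differences and truncated entries common in pooled database sequences,
#' where a mean would drift.
#'
#' @param peptide Non-empty peptide string.
#' @param records Protein record data.frame.
#' @return A list with `peptide`, `n_sequences` (number of records
#'   containing the peptide) and `median_position` (NA when no record
#'   contains it).
#' @export
peptide_median_position <- function(peptide, records) {
  stopifnot(nzchar(peptide))
  pos <- first_occurrence(peptide, records$sequence)
  pos <- pos[pos > 0L]
  list(peptide = peptide,
       n_sequences = length(pos),
       median_position = if (length(pos)) as.numeric(median(pos)) else NA_real_)
}

# 1-based first-occurrence positions (-1 when absent), fixed matching.
first_occurrence <- function(peptide, sequences) {
  if (length(sequences) == 0) return(integer(0))
  as.integer(regexpr(peptide, sequences, fixed = TRUE))
}

#' Positional profile of a peptide list
#'
#' One row per list peptide with its sequence support and median position.
#'
#' @param list A `peptide_list`.
#' @param records Protein record data.frame.
#' @return A data.frame `group_id`, `peptide`, `n_sequences`,
#'   `median_position`, in list rank order.
#' @export
peptide_profile <- function(list, records) {
  rows <- lapply(list$peptides, peptide_median_position, records = records)
  data.frame(group_id = list$group_id,
             peptide = vapply(rows, `[[`, character(1), "peptide"),
             n_sequences = vapply(rows, `[[`, integer(1), "n_sequences"),
             median_position = vapply(rows, `[[`, numeric(1), "median_position"),
             stringsAsFactors = FALSE)
}

#' Histogram of median positions of a group's conserved peptides
#'
#' Each list peptide present in at least one record contributes one count
#' to the bin containing its median position; bins are `[1, w]`,
#' `[w+1, 2w]`, ... for bin width `w`. The bin sums therefore never exceed
#' the list size, and peptides absent from all records contribute nowhere.
#'
#' @param list A `peptide_list`.
#' @param records Protein record data.frame.
#' @param bin_width Bin width in residues (default 20).
#' @return A data.frame `bin_start`, `bin_end`, `count` covering bins from
#'   position 1 to the largest observed median (zero rows if no peptide is
#'   present in any record).
#' @export
position_histogram <- function(list, records, bin_width = 20L) {
  stopifnot(bin_width >= 1)
  prof <- peptide_profile(list, records)
  med <- prof$median_position[prof$n_sequences > 0]
  if (length(med) == 0) {
    return(data.frame(bin_start = integer(0), bin_end = integer(0),
                      count = integer(0)))
  }
  idx <- floor((med - 1) / bin_width)          # 0-based bin index
  max_idx <- max(idx)
  counts <- tabulate(idx + 1L, nbins = max_idx + 1L)
  data.frame(bin_start = as.integer((0:max_idx) * bin_width + 1L),
             bin_end = as.integer((1:(max_idx + 1L)) * bin_width),
             count = as.integer(counts))
}

#' Find catalytic-serine motifs in a peptide list
#'
#' Scans every list peptide for 4-residue windows matching the
#' serine-hydrolase nucleophile elbow pattern G-x-S-x (e.g. GHSF, GRSG),
#' the context of the catalytic serine in alpha/beta-hydrolases. Each
#' matching (peptide, offset) pair is reported once.
#'
#' @param list A `peptide_list`.
#' @return A data.frame `group_id`, `peptide`, `motif`, `offset` (1-based
#'   offset of the motif within the peptide).
#' @export
find_serine_motifs <- function(list) {
  rows <- list()
  for (pep in list$peptides) {
    n <- nchar(pep)
    if (n < 4L) next
    for (off in seq_len(n - 3L)) {
      win <- substr(pep, off, off + 3L)
      if (substr(win, 1L, 1L) == "G" && substr(win, 3L, 3L) == "S") {
        rows[[length(rows) + 1L]] <- data.frame(
          group_id = list$group_id, peptide = pep, motif = win,
          offset = off, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(group_id = integer(0), peptide = character(0),
                      motif = character(0), offset = integer(0)))
  }
  do.call(rbind, rows)
}
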
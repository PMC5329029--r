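#' Global pairwise percent identity between two proteins
#'
#' Optimal Needleman-Wunsch global alignment with BLOSUM62 substitution
#' scores and affine gap penalties (a gap of length k costs
#' `gap_opening + k * gap_extension`). Percent identity is
#' 100 x (identical aligned residue pairs) / (alignment columns in which
#' both sequences hold a residue) — gap columns are excluded from the
#' denominator, so the value reflects the aligned core rather than length
#' differences.
#'
#' @param a,b Protein records (one-row data.frames) or plain amino-acid
#'   strings.
#' @param gap_opening,gap_extension Affine gap penalties (positive costs).
#' @return Percent identity in `[0, 100]`.
#' @export
global_identity <- function(a, b, gap_opening = 10, gap_extension = 0.5) {
  sa <- if (is.character(a)) a[1L] else a$sequence[1L]
  sb <- if (is.character(b)) b[1L] else b$sequence[1L]
  if (!nzchar(sa) || !nzchar(sb)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    sa, sb, type = "global", substitutionMatrix = blosum62(),
    gapOpening = gap_opening, gapExtension = gap_extension)
  aligned_identity(as.character(Biostrings::pattern(pa)),
                   as.character(Biostrings::subject(pa)))
}

# identity over columns where both sequences have residues
aligned_identity <- function(p, s) {
  pc <- strsplit(p, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  both <- pc != "-" & sc != "-"
  if (!any(both)) return(0)
  100 * sum(pc[both] == sc[both]) / sum(both)
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Pairwise identity matrix over a set of proteins
#'
#' All unordered pairs via [global_identity()]; the matrix is symmetric
#' with a diagonal of 100.
#'
#' @param records Protein record data.frame with at least two rows.
#' @inheritParams global_identity
#' @return A symmetric numeric matrix with row/column names from
#'   `records$id`.
#' @export
identity_matrix <- function(records, gap_opening = 10, gap_extension = 0.5) {
  n <- nrow(records)
  stopifnot(n >= 2)
  m <- matrix(100, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- global_identity(records$sequence[i], records$sequence[j],
                           gap_opening, gap_extension)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}
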
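# Independent brute-force oracles. These share only the stated contracts
# with the package code, not its implementation paths.

# Distinct-peptide hit count by window enumeration + set membership
# (implementation uses fixed-string grepl).
oracle_score <- function(sequence, peptides) {
  n <- nchar(sequence)
  if (length(peptides) == 0 || n == 0) return(0L)
  k <- nchar(peptides[1])
  if (n < k) return(0L)
  windows <- substring(sequence, 1:(n - k + 1), k:n)
  sum(peptides %in% windows)
}

# Median of first-occurrence positions by explicit sort-and-index.
oracle_median_position <- function(peptide, sequences) {
  pos <- vapply(sequences, function(s) {
    n <- nchar(s)
    k <- nchar(peptide)
    if (n < k) return(-1L)
    w <- substring(s, 1:(n - k + 1), k:n)
    hit <- which(w == peptide)
    if (length(hit)) hit[1] else -1L
  }, integer(1), USE.NAMES = FALSE)
  pos <- sort(pos[pos > 0])
  n <- length(pos)
  if (n == 0) return(NA_real_)
  if (n %% 2 == 1) as.numeric(pos[(n + 1) / 2])
  else (pos[n / 2] + pos[n / 2 + 1]) / 2
}

# Codon-by-codon translation via the genetic-code table (the package goes
# through Biostrings::translate instead).
.codon_map <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(unname(gc), names(gc))
})

oracle_translate <- function(dna) {
  n_codons <- nchar(dna) %/% 3
  if (n_codons == 0) return("")
  codons <- substring(dna, 3 * (0:(n_codons - 1)) + 1, 3 * (1:n_codons))
  aa <- .codon_map[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

oracle_revcomp <- function(dna) {
  comp <- chartr("ACGTN", "TGCAN", dna)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# Brute-force genome scan: own fragmentation loop, own translation, own
# stop-splitting. Returns the set of "strand peptide" strings.
oracle_scan_set <- function(genome_seq, fragment_length = 2000,
                            overlap = 100, min_len = 51) {
  len <- nchar(genome_seq)
  step <- fragment_length - overlap
  offs <- 0
  while (offs[length(offs)] + fragment_length < len) {
    offs <- c(offs, offs[length(offs)] + step)
  }
  out <- character(0)
  for (off in offs) {
    frag <- substr(genome_seq, off + 1, min(off + fragment_length, len))
    if (nchar(frag) < 3) next
    for (strand in c("+", "-")) {
      s <- if (strand == "+") frag else oracle_revcomp(frag)
      for (frame in 0:2) {
        aa <- oracle_translate(substr(s, frame + 1, nchar(s)))
        for (seg in strsplit(aa, "*", fixed = TRUE)[[1]]) {
          if (nchar(seg) >= min_len) {
            out <- c(out, paste(strand, seg))
          }
        }
      }
    }
  }
  sort(unique(out))
}

# Exhaustive global-alignment oracle for tiny sequences: enumerates every
# alignment, scores it with BLOSUM62 and affine gaps (gap of length k costs
# open + k * ext), and returns the optimal score plus the identities (over
# residue-residue columns) of all optimal alignments.
oracle_global_align <- function(a, b, open = 10, ext = 0.5) {
  sub <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- list(score = -Inf, idents = numeric(0))
  rec <- function(i, j, prev, score, nid, nmatchcol) {
    if (i == length(ac) && j == length(bc)) {
      ident <- if (nmatchcol > 0) 100 * nid / nmatchcol else 0
      if (score > best$score + 1e-9) {
        best <<- list(score = score, idents = ident)
      } else if (abs(score - best$score) <= 1e-9) {
        best$idents <<- unique(c(best$idents, ident))
      }
      return(invisible())
    }
    if (i < length(ac) && j < length(bc)) {
      rec(i + 1, j + 1, "M",
          score + sub[ac[i + 1], bc[j + 1]],
          nid + (ac[i + 1] == bc[j + 1]), nmatchcol + 1)
    }
    if (i < length(ac)) {
      rec(i + 1, j, "X", score - ext - if (prev != "X") open else 0,
          nid, nmatchcol)
    }
    if (j < length(bc)) {
      rec(i, j + 1, "Y", score - ext - if (prev != "Y") open else 0,
          nid, nmatchcol)
    }
  }
  rec(0, 0, "M", 0, 0, 0)
  best
}

# Adjusted Rand index of a clustering against planted labels; unclassified
# records count as singleton clusters.
clustering_ari <- function(groupset, truth_labels) {
  mt <- membership_table(groupset)
  pred <- mt$group_id[match(truth_labels$id, mt$protein_id)]
  miss <- is.na(pred)
  pred[miss] <- max(0L, pred, na.rm = TRUE) + seq_len(sum(miss))
  mclust::adjustedRandIndex(pred, truth_labels$group)
}
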
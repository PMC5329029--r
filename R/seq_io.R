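#' Read a protein FASTA file into a protein record table
#'
#' Sequences are uppercased, `*` characters and whitespace are stripped, and
#' any residue outside the 20 standard amino acids is mapped to `X`
#' (conservative matching: `X` never matches a conserved peptide). Entries
#' whose sequence is empty after cleaning are dropped with a warning.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A data.frame with columns `id` (first token of the header),
#'   `description` (remainder of the header, possibly empty) and `sequence`.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("protein FASTA not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  seqs <- gsub("[*[:space:]]", "", seqs)
  seqs <- clean_protein(seqs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  keep <- nzchar(seqs)
  if (any(!keep)) {
    warning(sum(!keep), " FASTA entr",
            if (sum(!keep) == 1) "y" else "ies",
            " with empty sequence dropped", call. = FALSE)
  }
  data.frame(id = ids[keep], description = desc[keep],
             sequence = unname(seqs[keep]), stringsAsFactors = FALSE)
}

#' Read a genome FASTA file
#'
#' DNA is uppercased; any base outside `A/C/G/T` is mapped to `N`.
#'
#' @param path Path to a FASTA file of nucleotide sequences.
#' @return A data.frame with columns `id`, `description`, `sequence`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("genome FASTA not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  seqs <- gsub("[[:space:]]", "", seqs)
  seqs <- vapply(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    chars[!chars %in% DNA_ALPHABET5] <- "N"
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  data.frame(id = ids, description = desc, sequence = seqs,
             stringsAsFactors = FALSE)
}

# Map any non-standard residue (B, Z, J, U, O, digits, ...) to 'X'.
clean_protein <- function(seqs) {
  vapply(seqs, function(s) {
    if (!nzchar(s)) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    chars[!chars %in% AA_ALPHABET21] <- "X"
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records Protein record data.frame (`id`, optional `description`,
#'   `sequence`).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(records$sequence)
  desc <- if ("description" %in% names(records)) records$description else ""
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Remove exact-sequence duplicates
#'
#' Duplicate means full-sequence string equality (not identifier equality):
#' pooled homolog searches typically return the same sequence under several
#' accessions. The first occurrence in input order is kept and output order
#' is stable.
#'
#' @param records Protein record data.frame.
#' @return The records with duplicated sequences removed.
#' @export
deduplicate_proteins <- function(records) {
  records[!duplicated(records$sequence), , drop = FALSE]
}

#' Filter protein records by minimum length
#'
#' Sequences shorter than `min_length` residues are removed (the curation
#' threshold used after unrelated domains have been excised upstream).
#'
#' @param records Protein record data.frame.
#' @param min_length Minimum sequence length kept, in residues (default 51).
#' @return The records whose sequences have at least `min_length` residues.
#' @export
filter_by_length <- function(records, min_length = 51L) {
  stopifnot(min_length >= 1)
  records[nchar(records$sequence) >= min_length, , drop = FALSE]
}

#' Curate protein records: deduplicate then length-filter
#'
#' @inheritParams filter_by_length
#' @param verbose Log record counts per curation step to stderr.
#' @return Curated records.
#' @export
curate_proteins <- function(records, min_length = 51L, verbose = TRUE) {
  n0 <- nrow(records)
  records <- deduplicate_proteins(records)
  n1 <- nrow(records)
  records <- filter_by_length(records, min_length)
  n2 <- nrow(records)
  if (anyDuplicated(records$id)) {
    stop("duplicate ids remain after curation; ids must be unique",
         call. = FALSE)
  }
  if (verbose) {
    message(sprintf("curate: %d input; %d after deduplication; %d after length >= %d",
                    n0, n1, n2, min_length))
  }
  records
}

#' Write a report table as TSV
#'
#' Tab-separated, header row, no quoting, no row names; callers are expected
#' to pass rows in a deterministic, documented order.
#'
#' @param rows A data.frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_table <- function(rows, path) {
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV report written by [write_table()]
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_table <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
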
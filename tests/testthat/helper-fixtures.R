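# Small fixture builders used across test files.

make_records <- function(seqs, ids = sprintf("p%d", seq_along(seqs))) {
  data.frame(id = ids, description = rep("", length(seqs)), sequence = seqs,
             stringsAsFactors = FALSE)
}

make_plist <- function(peptides, group_id = 1L,
                       frequency = rep(1L, length(peptides))) {
  structure(list(group_id = as.integer(group_id), peptides = peptides,
                 frequency = as.integer(frequency)),
            class = "peptide_list")
}

# A sequence of `len` filler residues with a peptide planted at `pos`
# (1-based). The filler residue must not occur in the peptide.
plant_peptide <- function(peptide, pos, len = 300, filler = "A") {
  stopifnot(pos + nchar(peptide) - 1 <= len)
  paste0(strrep(filler, pos - 1), peptide,
         strrep(filler, len - pos - nchar(peptide) + 1))
}

random_protein <- function(len, alphabet = c("A","C","D","E","F","G","H","I",
                                             "K","L","M","N","P","Q","R","S",
                                             "T","V","W","Y")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_dna_record <- function(len, id = "g") {
  data.frame(id = id, description = "", sequence = random_dna(len),
             stringsAsFactors = FALSE)
}

# Deterministic reverse translation (first codon alphabetically per residue);
# independent of the package's random synonymous-codon generator.
reverse_translate_fixture <- function(peptide) {
  gc <- Biostrings::GENETIC_CODE
  first_codon <- vapply(split(names(gc), unname(gc)), function(x) sort(x)[1],
                        character(1))
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  paste(first_codon[aa], collapse = "")
}

write_fasta_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Map planted family labels to PPR group ids by majority membership.
family_to_group <- function(groupset, truth_labels) {
  mt <- membership_table(groupset)
  fams <- sort(unique(truth_labels$group))
  setNames(vapply(fams, function(f) {
    ids <- truth_labels$id[truth_labels$group == f]
    gids <- mt$group_id[match(ids, mt$protein_id)]
    gids <- gids[!is.na(gids)]
    if (length(gids) == 0) return(NA_integer_)
    as.integer(names(sort(table(gids), decreasing = TRUE))[1])
  }, integer(1)), as.character(fams))
}
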
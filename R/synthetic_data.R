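#' Specification of a synthetic protein-family benchmark
#'
#' Describes families of proteins that share conserved hexapeptides inside
#' one or more motif regions (emulating a conserved catalytic region) while
#' the rest of the sequence diverges. Each family has a random consensus;
#' members copy it, mutating residues outside the motif regions at
#' `background_substitution_rate` and inside them at
#' `motif_substitution_rate` (a mutation always changes the residue).
#' Defaults place a single 40-residue motif region at `[160, 200)` in
#' 300-residue proteins — a conservation hotspot like the one observed for
#' glucuronoyl-esterase families — giving 35 fully conserved hexapeptide
#' windows per family at the default rates.
#'
#' @param n_groups Number of families.
#' @param members_per_group Sequences per family.
#' @param sequence_length Protein length in residues.
#' @param motif_regions List of 0-based half-open residue intervals
#'   `c(start, end)` where conservation concentrates.
#' @param background_substitution_rate Per-residue probability that a
#'   non-motif residue differs from the consensus.
#' @param motif_substitution_rate Same, inside motif regions.
#' @param alphabet Residue alphabet sampled for consensus and mutations.
#' @param seed Mandatory integer seed.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(n_groups = 3L,
                        members_per_group = 20L,
                        sequence_length = 300L,
                        motif_regions = list(c(160L, 200L)),
                        background_substitution_rate = 0.5,
                        motif_substitution_rate = 0.0,
                        alphabet = AA_STANDARD,
                        seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (is.numeric(motif_regions)) motif_regions <- list(motif_regions)
  for (r in motif_regions) {
    stopifnot(length(r) == 2, r[1] >= 0, r[2] > r[1],
              r[2] <= sequence_length)
  }
  stopifnot(background_substitution_rate >= 0, background_substitution_rate <= 1,
            motif_substitution_rate >= 0, motif_substitution_rate <= 1,
            n_groups >= 1, members_per_group >= 1, length(alphabet) >= 2)
  structure(list(n_groups = as.integer(n_groups),
                 members_per_group = as.integer(members_per_group),
                 sequence_length = as.integer(sequence_length),
                 motif_regions = motif_regions,
                 background_substitution_rate = background_substitution_rate,
                 motif_substitution_rate = motif_substitution_rate,
                 alphabet = alphabet,
                 seed = as.integer(seed)),
            class = "family_spec")
}

#' Number of guaranteed conserved hexapeptide windows of a family spec
#'
#' Windows of the given peptide length fully inside a motif region; with
#' `motif_substitution_rate = 0` these are shared by every family member.
#'
#' @param spec A [family_spec()].
#' @param peptide_length Peptide window length.
#' @return Integer count.
#' @export
motif_capacity <- function(spec, peptide_length = 6L) {
  as.integer(sum(vapply(spec$motif_regions, function(r) {
    max(0, as.numeric(r[2] - r[1]) - peptide_length + 1)
  }, numeric(1))))
}

#' Generate synthetic protein families with known ground truth
#'
#' Record ids are assigned in a shuffled order so they encode nothing about
#' family membership; the labels live only in the returned truth object.
#'
#' @param spec A [family_spec()].
#' @param peptides_per_group If supplied, require that [motif_capacity()]
#'   can fully populate a conserved-peptide list of this size and fail
#'   loudly otherwise (guards benchmarks that assume saturated lists).
#' @param peptide_length Peptide length used for the capacity check and
#'   the planted-motif inventory in the truth object.
#' @return A list with `records` (protein record data.frame) and `truth`:
#'   `labels` (data.frame `id`, `group`), `motifs` (data.frame `group`,
#'   `peptide`, `start` — consensus hexapeptides fully inside motif
#'   regions, 1-based starts) and `consensus` (named character).
#' @export
generate_families <- function(spec, peptides_per_group = NULL,
                              peptide_length = 6L) {
  cap <- motif_capacity(spec, peptide_length)
  if (!is.null(peptides_per_group) && cap < peptides_per_group) {
    stop(sprintf(paste0("family spec provides only %d guaranteed conserved ",
                        "%d-mers but %d peptides per group were requested; ",
                        "widen or add motif regions"),
                 cap, peptide_length, peptides_per_group), call. = FALSE)
  }
  withr::local_seed(spec$seed)
  L <- spec$sequence_length
  motif_mask <- rep(FALSE, L)
  for (r in spec$motif_regions) motif_mask[(r[1] + 1L):r[2]] <- TRUE

  consensus <- character(spec$n_groups)
  seqs <- character(0)
  labels <- integer(0)
  motif_rows <- list()
  for (g in seq_len(spec$n_groups)) {
    cons <- sample(spec$alphabet, L, replace = TRUE)
    consensus[g] <- paste(cons, collapse = "")
    rate <- ifelse(motif_mask, spec$motif_substitution_rate,
                   spec$background_substitution_rate)
    for (m in seq_len(spec$members_per_group)) {
      mut <- runif(L) < rate
      member <- cons
      if (any(mut)) {
        member[mut] <- vapply(cons[mut], function(orig) {
          sample(setdiff(spec$alphabet, orig), 1L)
        }, character(1))
      }
      seqs <- c(seqs, paste(member, collapse = ""))
      labels <- c(labels, g)
    }
    win <- extract_peptides(consensus[g], peptide_length)
    inside <- vapply(win$start, function(s) {
      all(motif_mask[s:(s + peptide_length - 1L)])
    }, logical(1))
    if (any(inside)) {
      motif_rows[[g]] <- data.frame(group = g,
                                    peptide = win$peptide[inside],
                                    start = win$start[inside],
                                    stringsAsFactors = FALSE)
    }
  }
  ord <- sample(length(seqs))
  ids <- sprintf("prot%04d", seq_along(seqs))
  records <- data.frame(id = ids,
                        description = "",
                        sequence = seqs[ord],
                        stringsAsFactors = FALSE)
  truth <- list(labels = data.frame(id = ids, group = labels[ord],
                                    stringsAsFactors = FALSE),
                motifs = do.call(rbind, motif_rows),
                consensus = setNames(consensus,
                                     paste0("group", seq_len(spec$n_groups))))
  list(records = records, truth = truth)
}

#' Generate a synthetic genome with planted genes
#'
#' Each gene is a stop-free peptide reverse-translated with uniformly
#' random synonymous codons, flanked by one stop codon on each side, and
#' embedded on a randomly chosen strand; genes are separated (and the
#' genome flanked) by random intergenic DNA of the given length. The truth
#' records the coding interval of each gene in 0-based half-open forward
#' coordinates, so that translating `[start, end)` (reverse-complemented
#' for `-` strand genes) reproduces the peptide exactly.
#'
#' @param genes A data.frame with columns `peptide` (stop-free amino-acid
#'   strings over the 20 standard residues) and `group` (integer label
#'   carried into the truth), or NULL/zero rows for pure random DNA.
#' @param intergenic_length Bases of random DNA between and around genes.
#' @param seed Mandatory integer seed.
#' @param genome_id Identifier of the generated genome.
#' @return A list with `genome` (one-row genome record data.frame) and
#'   `truth` (data.frame `genome_id`, `group`, `strand`, `start`, `end`,
#'   `peptide`).
#' @export
generate_genome <- function(genes = NULL, intergenic_length = 500L, seed,
                            genome_id = "synthetic_genome") {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  withr::local_seed(seed)
  if (is.null(genes)) {
    genes <- data.frame(peptide = character(0), group = integer(0))
  }
  codon_table <- synonymous_codons()
  stops <- c("TAA", "TAG", "TGA")
  parts <- character(0)
  truth <- list()
  pos <- 0L
  for (i in seq_len(nrow(genes) + 1L)) {
    inter <- paste(sample(c("A", "C", "G", "T"), intergenic_length,
                          replace = TRUE), collapse = "")
    parts <- c(parts, inter)
    pos <- pos + intergenic_length
    if (i > nrow(genes)) break
    pep <- genes$peptide[i]
    cds <- reverse_translate(pep, codon_table)
    block <- paste0(sample(stops, 1L), cds, sample(stops, 1L))
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") {
      block <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(block)))
    }
    cds_len <- 3L * nchar(pep)
    # block = stop + cds + stop on its own strand; on the forward strand the
    # cds always sits 3 bases in from the block start
    truth[[i]] <- data.frame(genome_id = genome_id, group = genes$group[i],
                             strand = strand,
                             start = pos + 3L,
                             end = pos + 3L + cds_len,
                             peptide = pep, stringsAsFactors = FALSE)
    parts <- c(parts, block)
    pos <- pos + nchar(block)
  }
  genome <- data.frame(id = genome_id, description = "",
                       sequence = paste(parts, collapse = ""),
                       stringsAsFactors = FALSE)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(genome_id = character(0), group = integer(0),
               strand = character(0), start = integer(0), end = integer(0),
               peptide = character(0), stringsAsFactors = FALSE)
  list(genome = genome, truth = truth)
}

# standard-code codons per amino acid, stops excluded
synonymous_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

reverse_translate <- function(peptide, codon_table) {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  bad <- setdiff(aa, names(codon_table))
  if (length(bad)) {
    stop("cannot reverse-translate residues: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  paste(vapply(aa, function(a) {
    cods <- codon_table[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}
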
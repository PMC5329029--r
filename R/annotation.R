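#' Genome scan parameters
#'
#' Defaults follow the published crude-ORF genome screen: 2000-base
#' fragments with 100-base overlap, six-frame translation, and stop-free
#' translated segments of at least 51 residues ("longer than 50 residues")
#' kept for scoring. No start codon is required.
#'
#' @param fragment_length Fragment size in bases.
#' @param overlap Overlap between consecutive fragments in bases.
#' @param min_orf_residues Minimum translated segment length kept.
#' @param translation_table Genetic code id (only the standard code, 1, is
#'   supported).
#' @return An object of class `genome_scan_params`.
#' @export
genome_scan_params <- function(fragment_length = 2000L,
                               overlap = 100L,
                               min_orf_residues = 51L,
                               translation_table = 1L) {
  stopifnot(overlap >= 0, overlap < fragment_length, min_orf_residues >= 1)
  if (translation_table != 1L) {
    stop("only the standard genetic code (translation_table = 1) is supported",
         call. = FALSE)
  }
  structure(list(fragment_length = as.integer(fragment_length),
                 overlap = as.integer(overlap),
                 min_orf_residues = as.integer(min_orf_residues),
                 translation_table = 1L),
            class = "genome_scan_params")
}

#' Annotate proteins against group-specific peptide lists
#'
#' Each protein is scored against every peptide list (distinct-substring
#' count, as in [score_protein()]) and assigned to the group with the
#' highest score, provided that score reaches `min_score` and the maximum
#' is unique. Ties at the maximum are flagged `ambiguous`; sub-threshold
#' maxima are `unassigned`.
#'
#' @param records Protein record data.frame.
#' @param lists List of `peptide_list` objects with distinct group ids.
#' @param min_score Minimum best score required for assignment.
#' @return An object of class `ppr_annotation`: list with `assignments`
#'   (data.frame `id`, `best_group`, `score`, `status`) and `scores`
#'   (integer matrix, proteins x groups).
#' @export
annotate_proteins <- function(records, lists, min_score = 5L) {
  gids <- vapply(lists, `[[`, integer(1), "group_id")
  if (length(gids) == 0) stop("no peptide lists supplied", call. = FALSE)
  if (anyDuplicated(gids)) {
    stop("peptide lists carry duplicate group ids", call. = FALSE)
  }
  scores <- vapply(lists, function(pl) {
    score_sequences(records$sequence, pl$peptides)
  }, integer(nrow(records)))
  if (nrow(records) == 1L) scores <- matrix(scores, nrow = 1L)
  dimnames(scores) <- list(records$id, as.character(gids))
  assignments <- assign_best_group(records$id, scores, gids, min_score)
  structure(list(assignments = assignments, scores = scores,
                 min_score = as.integer(min_score)),
            class = "ppr_annotation")
}

# Shared argmax-with-threshold rule for proteins and ORF hits.
assign_best_group <- function(ids, scores, gids, min_score) {
  n <- length(ids)
  best_group <- rep(NA_integer_, n)
  best_score <- rep(0L, n)
  status <- rep("unassigned", n)
  if (n > 0 && length(gids) > 0) {
    for (i in seq_len(n)) {
      s <- scores[i, ]
      m <- max(s)
      best_score[i] <- as.integer(m)
      if (m >= min_score) {
        at_max <- which(s == m)
        if (length(at_max) == 1L) {
          best_group[i] <- gids[at_max]
          status[i] <- "assigned"
        } else {
          status[i] <- "ambiguous"
        }
      }
    }
  }
  data.frame(id = ids, best_group = best_group, score = best_score,
             status = status, stringsAsFactors = FALSE)
}

#' @export
print.ppr_annotation <- function(x, ...) {
  tab <- table(x$assignments$status)
  cat(sprintf("<ppr_annotation> %d sequences vs %d peptide lists (min_score %d)\n",
              nrow(x$assignments), ncol(x$scores), x$min_score))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Split a genome into overlapping fragments
#'
#' Fragments start at 0, 0 + step, 0 + 2*step, ... with step
#' `fragment_length - overlap`, until the genome end is covered; the last
#' fragment may be shorter. Fragments shorter than one codon are dropped.
#'
#' @param genome A single genome record (one row: `id`, `sequence`) or a
#'   DNA string.
#' @param params A [genome_scan_params()] object.
#' @return A data.frame with `offset` (0-based) and `sequence`.
#' @export
fragment_genome <- function(genome, params = genome_scan_params()) {
  seq <- if (is.character(genome)) genome[1L] else genome$sequence[1L]
  len <- nchar(seq)
  step <- params$fragment_length - params$overlap
  offsets <- 0L
  while (offsets[length(offsets)] + params$fragment_length < len) {
    offsets <- c(offsets, offsets[length(offsets)] + step)
  }
  frags <- substring(seq, offsets + 1L,
                     pmin(offsets + params$fragment_length, len))
  keep <- nchar(frags) >= 3L
  data.frame(offset = offsets[keep], sequence = frags[keep],
             stringsAsFactors = FALSE)
}

#' Six-frame translated segments of one genome fragment
#'
#' Translates the fragment in all three forward and three
#' reverse-complement frames with the standard genetic code, splits each
#' translation at stop codons, and keeps maximal stop-free segments of at
#' least `min_orf_residues` residues. Segments truncated by the fragment
#' edge (no flanking stop visible) are kept; codons containing `N`
#' translate to `X`, which is retained in the peptide but never matches a
#' list peptide. Coordinates are reported 0-based half-open on the forward
#' strand of the genome.
#'
#' @param fragment One row of [fragment_genome()] output (or a list with
#'   `offset` and `sequence`).
#' @param params A [genome_scan_params()] object.
#' @param genome_id Genome identifier carried into the hits.
#' @return A data.frame of ORF hits: `genome_id`, `fragment_offset`,
#'   `strand`, `frame`, `peptide`, `length_aa`, `genome_start`,
#'   `genome_end`.
#' @export
six_frame_orfs <- function(fragment, params = genome_scan_params(),
                           genome_id = NA_character_) {
  frames <- frame_table(fragment$offset[1L], fragment$sequence[1L])
  frames$aa <- translate_frames(frames$sub)
  orf_hits_from_frames(frames, params, genome_id)
}

# The six frame subsequences of one fragment (in-frame, codon-trimmed).
frame_table <- function(off, dna) {
  len <- nchar(dna)
  rc <- if (len > 0) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  } else {
    ""
  }
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else rc
    for (frame in 0:2) {
      n_codons <- (len - frame) %/% 3L
      if (n_codons < 1L) next
      rows[[length(rows) + 1L]] <- data.frame(
        offset = off, frag_len = len, strand = strand, frame = frame,
        sub = substr(s, frame + 1L, frame + 3L * n_codons),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(offset = integer(0), frag_len = integer(0),
                      strand = character(0), frame = integer(0),
                      sub = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# One batched translate call: rebuilding the fuzzy genetic code per call
# dominates runtime otherwise.
translate_frames <- function(subs) {
  if (length(subs) == 0) return(character(0))
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAStringSet(subs), no.init.codon = TRUE,
    if.fuzzy.codon = "X")))
}

orf_hits_from_frames <- function(frames, params, genome_id) {
  out <- list()
  for (i in seq_len(nrow(frames))) {
    segs <- orf_segments(frames$aa[i], params$min_orf_residues)
    if (nrow(segs) == 0) next
    off <- frames$offset[i]
    len <- frames$frag_len[i]
    frame <- frames$frame[i]
    # aa positions (1-based) -> fragment nucleotides -> forward genome coords
    nt_start <- frame + 3L * (segs$aa_start - 1L)         # 0-based in frame seq
    nt_end <- frame + 3L * segs$aa_end                    # half-open
    if (frames$strand[i] == "+") {
      gstart <- off + nt_start
      gend <- off + nt_end
    } else {
      gstart <- off + len - nt_end
      gend <- off + len - nt_start
    }
    out[[length(out) + 1L]] <- data.frame(
      genome_id = genome_id, fragment_offset = off,
      strand = frames$strand[i], frame = frame, peptide = segs$peptide,
      length_aa = nchar(segs$peptide),
      genome_start = gstart, genome_end = gend,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(genome_id = character(0), fragment_offset = integer(0),
                      strand = character(0), frame = integer(0),
                      peptide = character(0), length_aa = integer(0),
                      genome_start = integer(0), genome_end = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Maximal stop-free runs of a translated frame, with 1-based aa coordinates.
orf_segments <- function(aa, min_len) {
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  stops <- c(0L, which(chars == "*"), length(chars) + 1L)
  starts <- stops[-length(stops)] + 1L
  ends <- stops[-1L] - 1L
  keep <- which((ends - starts + 1L) >= min_len)
  if (length(keep) == 0) {
    return(data.frame(aa_start = integer(0), aa_end = integer(0),
                      peptide = character(0), stringsAsFactors = FALSE))
  }
  data.frame(aa_start = starts[keep], aa_end = ends[keep],
             peptide = substring(aa, starts[keep], ends[keep]),
             stringsAsFactors = FALSE)
}

#' Scan a raw genome against group-specific peptide lists
#'
#' Fragments the genome, extracts six-frame translated segments, collapses
#' duplicate segments rediscovered in fragment overlaps (same strand and
#' genome coordinates), scores every segment against every peptide list and
#' assigns each to its best group under the [annotate_proteins()] rules.
#' Hits are sorted by `genome_start`, then strand.
#'
#' @param genome A single genome record (one row) or DNA string; when a
#'   bare string is given the genome id is `"genome"`.
#' @param lists List of `peptide_list` objects.
#' @param params A [genome_scan_params()] object.
#' @param min_score Minimum best score for group assignment.
#' @return A data.frame of ORF hits with scoring columns `best_group`,
#'   `score`, `status`; the full score matrix is attached as attribute
#'   `"scores"`.
#' @export
scan_genome <- function(genome, lists, params = genome_scan_params(),
                        min_score = 5L) {
  gid <- if (is.character(genome)) "genome" else genome$id[1L]
  frags <- fragment_genome(genome, params)
  frames <- do.call(rbind, lapply(seq_len(nrow(frags)), function(i) {
    frame_table(frags$offset[i], frags$sequence[i])
  }))
  if (is.null(frames)) frames <- frame_table(0L, "")
  frames$aa <- translate_frames(frames$sub)
  hits <- orf_hits_from_frames(frames, params, gid)
  dup <- duplicated(hits[, c("strand", "genome_start", "genome_end")])
  hits <- hits[!dup, , drop = FALSE]
  hits <- hits[order(hits$genome_start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  gids <- vapply(lists, `[[`, integer(1), "group_id")
  if (anyDuplicated(gids)) {
    stop("peptide lists carry duplicate group ids", call. = FALSE)
  }
  scores <- vapply(lists, function(pl) {
    score_sequences(hits$peptide, pl$peptides)
  }, integer(nrow(hits)))
  if (nrow(hits) == 1L) scores <- matrix(scores, nrow = 1L)
  assign <- assign_best_group(seq_len(nrow(hits)), scores, gids, min_score)
  hits$best_group <- assign$best_group
  hits$score <- assign$score
  hits$status <- assign$status
  attr(scores, "dimnames") <- list(NULL, as.character(gids))
  attr(hits, "scores") <- scores
  hits
}

#' Export genome-scan hits as BED6
#'
#' One line per assigned hit: chrom, 0-based half-open interval, name =
#' group id, score capped at 1000, strand.
#'
#' @param hits Output of [scan_genome()].
#' @param path Output file path.
#' @param assigned_only Keep only hits with an assigned group.
#' @return The path, invisibly.
#' @export
write_hits_bed <- function(hits, path, assigned_only = TRUE) {
  if (assigned_only) hits <- hits[hits$status == "assigned", , drop = FALSE]
  bed <- data.frame(chrom = hits$genome_id,
                    start = hits$genome_start,
                    end = hits$genome_end,
                    name = ifelse(is.na(hits$best_group), ".",
                                  paste0("group", hits$best_group)),
                    score = pmin(hits$score, 1000L),
                    strand = hits$strand,
                    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-class averages of assigned gene counts
#'
#' Aggregates annotation results over organisms grouped by a class label
#' (e.g. coprophilic fungi, white/gray/brown rot fungi, bacteria): for each
#' class, the arithmetic mean over its organisms of the number of assigned
#' sequences, overall and per group.
#'
#' @param results A data.frame with one row per organism: columns
#'   `organism`, `class`, and `annotation` as a list-column of
#'   `ppr_annotation` objects or [scan_genome()] hit tables; alternatively
#'   pass `organisms`, `classes`, `annotations` separately.
#' @param organisms,classes,annotations Parallel vectors/list used when
#'   `results` is NULL.
#' @return A data.frame with `class`, `group` (`"all"` for the overall
#'   mean, otherwise the group id) and `mean_count`, ordered by class then
#'   group.
#' @export
summarize_by_class <- function(results = NULL, organisms = NULL,
                               classes = NULL, annotations = NULL) {
  if (!is.null(results)) {
    organisms <- results$organism
    classes <- results$class
    annotations <- results$annotation
  }
  if (any(is.na(classes)) || any(!nzchar(classes))) {
    stop("every organism must carry exactly one class label", call. = FALSE)
  }
  counts <- lapply(annotations, assigned_group_counts)
  all_groups <- sort(unique(unlist(lapply(counts, names))))
  rows <- list()
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    per_org_total <- vapply(counts[idx], sum, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      class = cl, group = "all", mean_count = mean(per_org_total),
      stringsAsFactors = FALSE)
    for (g in all_groups) {
      per_org <- vapply(counts[idx], function(x) {
        if (g %in% names(x)) x[[g]] else 0
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, group = g, mean_count = mean(per_org),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

assigned_group_counts <- function(ann) {
  df <- if (inherits(ann, "ppr_annotation")) ann$assignments else ann
  df <- df[df$status == "assigned", , drop = FALSE]
  if (nrow(df) == 0) return(setNames(numeric(0), character(0)))
  tab <- table(df$best_group)
  setNames(as.numeric(tab), names(tab))
}
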
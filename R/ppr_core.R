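#' Clustering parameters for peptide pattern recognition
#'
#' The three numbers that define a PPR run: the peptide (k-mer) length, the
#' number of list peptides a protein must contain to be a group member, and
#' the size cap of each group's conserved-peptide list. Defaults are the
#' published CE15 settings (6 / 10 / 70).
#'
#' @param peptide_length Length of the conserved peptides in residues.
#' @param peptides_per_protein Minimum number of distinct list peptides a
#'   sequence must contain to belong to a group.
#' @param peptides_per_group Maximum number of peptides in a group list.
#' @param min_group_size Minimum members for a group to be reported.
#' @param max_iterations Cap on list/membership refinement iterations.
#' @return An object of class `ppr_params`.
#' @export
ppr_params <- function(peptide_length = 6L,
                       peptides_per_protein = 10L,
                       peptides_per_group = 70L,
                       min_group_size = 2L,
                       max_iterations = 100L) {
  p <- list(peptide_length = as.integer(peptide_length),
            peptides_per_protein = as.integer(peptides_per_protein),
            peptides_per_group = as.integer(peptides_per_group),
            min_group_size = as.integer(min_group_size),
            max_iterations = as.integer(max_iterations))
  stopifnot(all(unlist(p) >= 1),
            p$peptides_per_protein <= p$peptides_per_group)
  structure(p, class = "ppr_params")
}

#' Extract all peptide windows from a sequence
#'
#' All overlapping windows of the given length with 1-based start positions.
#' Windows containing `X` are excluded: `X` marks a non-standard or unknown
#' residue and never matches a conserved peptide.
#'
#' @param sequence Amino-acid string.
#' @param length Window length (>= 1).
#' @return A data.frame with columns `peptide` and `start`; zero rows when
#'   the sequence is shorter than `length`.
#' @export
extract_peptides <- function(sequence, length = 6L) {
  stopifnot(length >= 1)
  n <- nchar(sequence)
  if (n < length) {
    return(data.frame(peptide = character(0), start = integer(0),
                      stringsAsFactors = FALSE))
  }
  starts <- seq_len(n - length + 1L)
  peps <- substring(sequence, starts, starts + length - 1L)
  keep <- !grepl("X", peps, fixed = TRUE)
  data.frame(peptide = peps[keep], start = starts[keep],
             stringsAsFactors = FALSE)
}

#' Count, for each peptide, the number of proteins containing it
#'
#' Presence counting: a peptide occurring several times within one protein
#' still counts once for that protein. Conservation is measured across
#' sequences, not by copy number.
#'
#' @param records Protein record data.frame.
#' @param length Peptide length.
#' @return A named integer vector, peptide -> number of proteins.
#' @export
peptide_protein_frequency <- function(records, length = 6L) {
  if (nrow(records) == 0) return(integer(0))
  per_protein <- lapply(records$sequence, function(s) {
    unique(extract_peptides(s, length)$peptide)
  })
  tab <- table(unlist(per_protein))
  setNames(as.integer(tab), names(tab))
}

#' Derive a group's conserved-peptide list
#'
#' The `peptides_per_group` most protein-frequent peptides among the given
#' records; ties at the cap boundary are broken by ascending lexicographic
#' order so the list is deterministic. Fewer peptides are returned when
#' fewer distinct peptides exist.
#'
#' @param records Protein record data.frame (the group members).
#' @param params A [ppr_params()] object.
#' @param group_id Integer group identifier stored in the list.
#' @return An object of class `peptide_list`: list with `group_id`,
#'   `peptides` (character, ranked) and `frequency` (integer, parallel).
#' @export
derive_peptide_list <- function(records, params = ppr_params(), group_id = 1L) {
  stopifnot(nrow(records) > 0)
  freq <- peptide_protein_frequency(records, params$peptide_length)
  new_peptide_list(freq, params, group_id)
}

new_peptide_list <- function(freq, params, group_id) {
  if (length(freq) > 0) {
    ord <- order(-freq, names(freq), method = "radix")
    freq <- freq[ord]
    n <- min(length(freq), params$peptides_per_group)
    freq <- freq[seq_len(n)]
  }
  structure(list(group_id = as.integer(group_id),
                 peptides = names(freq),
                 frequency = unname(as.integer(freq))),
            class = "peptide_list")
}

#' @export
print.peptide_list <- function(x, ...) {
  cat(sprintf("<peptide_list> group %d: %d peptides\n",
              x$group_id, length(x$peptides)))
  if (length(x$peptides)) {
    shown <- head(sprintf("%s(%d)", x$peptides, x$frequency), 8)
    cat("  ", paste(shown, collapse = " "),
        if (length(x$peptides) > 8) "..." else "", "\n")
  }
  invisible(x)
}

#' Score a sequence against a peptide list
#'
#' The number of distinct list peptides occurring as substrings of the
#' sequence; copy number is ignored.
#'
#' @param sequence Amino-acid string.
#' @param list A `peptide_list`.
#' @return An integer score between 0 and `length(list$peptides)`.
#' @export
score_protein <- function(sequence, list) {
  score_sequences(sequence, list$peptides)[1L]
}

# Vectorized scoring: distinct-peptide hit count per sequence.
score_sequences <- function(sequences, peptides) {
  if (length(peptides) == 0 || length(sequences) == 0) {
    return(integer(length(sequences)))
  }
  hits <- vapply(peptides, function(p) grepl(p, sequences, fixed = TRUE),
                 logical(length(sequences)))
  if (length(sequences) == 1L) hits <- matrix(hits, nrow = 1L)
  as.integer(rowSums(hits))
}

#' Form one PPR group from a working set of proteins
#'
#' Seed-and-refine: the seed members are all proteins containing the single
#' most protein-frequent peptide (ties broken lexicographically). The
#' conserved-peptide list is then derived from the members and the member
#' set redefined as all working proteins containing at least
#' `peptides_per_protein` list peptides, iterating until the member set
#' repeats. If the iteration oscillates instead of stabilizing, the visited
#' state with the most members (earliest on ties) is kept. The final member
#' set is always the score-filter of the reported list, so the membership
#' contract (member score >= `peptides_per_protein`) holds by construction.
#'
#' @param working Protein record data.frame (unassigned proteins).
#' @param params A [ppr_params()] object.
#' @param group_id Group identifier to assign.
#' @return A list with `group` (NULL if no group of at least
#'   `min_group_size` members could be formed) and `remaining` (records not
#'   absorbed into the group). A `group` is a list with `group_id`,
#'   `members` (ids), `peptide_list` and `scores` (named integer).
#' @export
form_group <- function(working, params = ppr_params(), group_id = 1L) {
  stopifnot(nrow(working) > 0)
  freq <- peptide_protein_frequency(working, params$peptide_length)
  if (length(freq) == 0) {
    return(list(group = NULL, remaining = working))
  }
  top <- sort(names(freq)[freq == max(freq)])[1L]
  members <- working$id[grepl(top, working$sequence, fixed = TRUE)]

  seen <- list()
  state_key <- function(ids) paste(sort(ids), collapse = "\r")
  plist <- NULL
  for (iter in seq_len(params$max_iterations)) {
    seen[[length(seen) + 1L]] <- members
    plist <- derive_peptide_list(working[working$id %in% members, , drop = FALSE],
                                 params, group_id)
    scores <- score_sequences(working$sequence, plist$peptides)
    members_new <- working$id[scores >= params$peptides_per_protein]
    if (length(members_new) == 0) {
      return(list(group = NULL, remaining = working))
    }
    if (state_key(members_new) %in% vapply(seen, state_key, character(1))) {
      if (state_key(members_new) != state_key(members)) {
        # oscillation: keep the visited state with most members (earliest tie)
        sizes <- lengths(seen)
        best <- seen[[which.max(sizes)]]
        plist <- derive_peptide_list(
          working[working$id %in% best, , drop = FALSE], params, group_id)
      }
      break
    }
    members <- members_new
  }
  # final membership is always the score-filter of the reported list
  scores <- score_sequences(working$sequence, plist$peptides)
  keep <- scores >= params$peptides_per_protein
  members <- working$id[keep]
  if (length(members) < params$min_group_size) {
    return(list(group = NULL, remaining = working))
  }
  list(group = list(group_id = as.integer(group_id),
                    members = members,
                    peptide_list = plist,
                    scores = setNames(scores[keep], members)),
       remaining = working[!keep, , drop = FALSE])
}

#' Cluster proteins into PPR groups
#'
#' Repeatedly forms groups from the remaining unassigned proteins, numbering
#' them 1, 2, 3, ... in formation order, until no further group of at least
#' `min_group_size` members can be formed; leftovers become the unclassified
#' set. The procedure is deterministic for a fixed input order, and the
#' result partitions the input: every protein is in exactly one group or in
#' `unclassified`.
#'
#' @param records Curated protein record data.frame (unique ids).
#' @param params A [ppr_params()] object.
#' @return An object of class `ppr_groupset`: list with `groups` (list of
#'   group objects as from [form_group()]), `unclassified` (ids) and
#'   `params`.
#' @export
ppr_cluster <- function(records, params = ppr_params()) {
  if (anyDuplicated(records$id)) {
    stop("record ids must be unique; curate inputs first", call. = FALSE)
  }
  groups <- list()
  working <- records
  gid <- 1L
  while (nrow(working) > 0) {
    res <- form_group(working, params, gid)
    if (is.null(res$group)) break
    groups[[gid]] <- res$group
    working <- res$remaining
    gid <- gid + 1L
  }
  structure(list(groups = groups,
                 unclassified = working$id,
                 params = params),
            class = "ppr_groupset")
}

#' @export
print.ppr_groupset <- function(x, ...) {
  cat(sprintf("<ppr_groupset> %d groups, %d unclassified\n",
              length(x$groups), length(x$unclassified)))
  for (g in x$groups) {
    cat(sprintf("  group %d: %d members, %d peptides\n",
                g$group_id, length(g$members), length(g$peptide_list$peptides)))
  }
  invisible(x)
}

#' Group membership of each input protein
#'
#' @param groupset A `ppr_groupset`.
#' @return A data.frame with `protein_id`, `group_id` (NA when unclassified)
#'   and `score`, groups first in group order then unclassified, members in
#'   their group's stored order.
#' @export
membership_table <- function(groupset) {
  rows <- lapply(groupset$groups, function(g) {
    data.frame(protein_id = g$members, group_id = g$group_id,
               score = unname(g$scores), stringsAsFactors = FALSE)
  })
  n_uncl <- length(groupset$unclassified)
  uncl <- data.frame(protein_id = groupset$unclassified,
                     group_id = rep(NA_integer_, n_uncl),
                     score = rep(NA_integer_, n_uncl),
                     stringsAsFactors = FALSE)
  do.call(rbind, c(rows, list(uncl)))
}

#' Peptide lists of a group set as one table
#'
#' @param x A `ppr_groupset` or a list of `peptide_list` objects.
#' @return A data.frame with `group_id`, `rank`, `peptide`,
#'   `protein_frequency`, ordered by group then rank.
#' @export
peptide_list_table <- function(x) {
  lists <- if (inherits(x, "ppr_groupset")) {
    lapply(x$groups, `[[`, "peptide_list")
  } else {
    x
  }
  rows <- lapply(lists, function(pl) {
    if (length(pl$peptides) == 0) return(NULL)
    data.frame(group_id = pl$group_id,
               rank = seq_along(pl$peptides),
               peptide = pl$peptides,
               protein_frequency = pl$frequency,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group_id = integer(0), rank = integer(0),
                      peptide = character(0), protein_frequency = integer(0))
  }
  out
}

#' Rebuild `peptide_list` objects from a [peptide_list_table()] data.frame
#'
#' @param tab Data.frame with columns `group_id`, `rank`, `peptide` and
#'   optionally `protein_frequency`.
#' @return A list of `peptide_list` objects, one per group id.
#' @export
peptide_lists_from_table <- function(tab) {
  lapply(sort(unique(tab$group_id)), function(g) {
    sub <- tab[tab$group_id == g, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    freq <- if ("protein_frequency" %in% names(sub)) {
      as.integer(sub$protein_frequency)
    } else {
      rep(NA_integer_, nrow(sub))
    }
    structure(list(group_id = as.integer(g),
                   peptides = sub$peptide,
                   frequency = freq),
              class = "peptide_list")
  })
}
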
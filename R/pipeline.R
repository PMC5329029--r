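#' Build a fully populated run configuration
#'
#' Merges user settings over defaults so the persisted copy always equals
#' the effective values. Paths: `proteins` (required FASTA), optional
#' `genome` FASTA, and `out_dir` for all reports.
#'
#' @param proteins Path to the input protein FASTA.
#' @param out_dir Output directory (created if missing).
#' @param genome Optional path to a genome FASTA to scan.
#' @param peptide_length,peptides_per_protein,peptides_per_group,min_group_size
#'   Clustering parameters, see [ppr_params()].
#' @param min_length Curation length threshold, see [filter_by_length()].
#' @param min_score Annotation score threshold.
#' @param fragment_length,overlap,min_orf_residues Genome-scan parameters,
#'   see [genome_scan_params()].
#' @param bin_width Histogram bin width for the positional profile.
#' @param seed Seed recorded in the config (the pipeline itself is
#'   deterministic; the seed matters when inputs are simulated upstream).
#' @return A `run_config` list.
#' @export
run_config <- function(proteins, out_dir, genome = NULL,
                       peptide_length = 6L, peptides_per_protein = 10L,
                       peptides_per_group = 70L, min_group_size = 2L,
                       min_length = 51L, min_score = 5L,
                       fragment_length = 2000L, overlap = 100L,
                       min_orf_residues = 51L, bin_width = 20L, seed = 1L) {
  structure(list(proteins = proteins, genome = genome, out_dir = out_dir,
                 peptide_length = as.integer(peptide_length),
                 peptides_per_protein = as.integer(peptides_per_protein),
                 peptides_per_group = as.integer(peptides_per_group),
                 min_group_size = as.integer(min_group_size),
                 min_length = as.integer(min_length),
                 min_score = as.integer(min_score),
                 fragment_length = as.integer(fragment_length),
                 overlap = as.integer(overlap),
                 min_orf_residues = as.integer(min_orf_residues),
                 bin_width = as.integer(bin_width),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration (YAML)
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `write_run_config` the path invisibly; `read_run_config` a
#'   `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[!vapply(vals, is.null, logical(1))])
}

#' Run the full classification pipeline
#'
#' Curate the input proteins, cluster them into peptide-defined groups,
#' write the peptide lists, group membership, positional profile and
#' serine-motif reports, optionally scan a genome, and record a manifest
#' of every output with its row count. All reports are TSV with
#' deterministic row order, so a rerun with the same config is
#' byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `ppr_groupset`, the curated records,
#'   genome hits (or NULL) and the manifest data.frame.
#' @export
run_pipeline <- function(config) {
  if (!file.exists(config$proteins)) {
    stop("input protein FASTA not found: ", config$proteins, call. = FALSE)
  }
  if (!is.null(config$genome) && !file.exists(config$genome)) {
    stop("genome FASTA not found: ", config$genome, call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(msg) {
    message(sprintf("[%5.1fs] %s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")), msg))
  }
  outputs <- list()
  emit <- function(name, rows) {
    path <- file.path(config$out_dir, name)
    write_table(rows, path)
    outputs[[name]] <<- nrow(rows)
    rows
  }

  stage("reading and curating proteins")
  records <- read_protein_fasta(config$proteins)
  records <- curate_proteins(records, min_length = config$min_length)

  stage("clustering")
  params <- ppr_params(peptide_length = config$peptide_length,
                       peptides_per_protein = config$peptides_per_protein,
                       peptides_per_group = config$peptides_per_group,
                       min_group_size = config$min_group_size)
  groupset <- ppr_cluster(records, params)

  stage("writing cluster reports")
  emit("peptide_lists.tsv", peptide_list_table(groupset))
  emit("membership.tsv", membership_table(groupset))

  stage("positional profile and serine motifs")
  prof <- do.call(rbind, lapply(groupset$groups, function(g) {
    peptide_profile(g$peptide_list, records[records$id %in% g$members, ,
                                            drop = FALSE])
  }))
  if (is.null(prof)) {
    prof <- data.frame(group_id = integer(0), peptide = character(0),
                       n_sequences = integer(0), median_position = numeric(0))
  }
  emit("peptide_profile.tsv", prof)
  motifs <- do.call(rbind, lapply(groupset$groups, function(g) {
    find_serine_motifs(g$peptide_list)
  }))
  if (is.null(motifs)) {
    motifs <- data.frame(group_id = integer(0), peptide = character(0),
                         motif = character(0), offset = integer(0))
  }
  emit("serine_motifs.tsv", motifs)

  hits <- NULL
  if (!is.null(config$genome)) {
    stage("genome scan")
    scan_params <- genome_scan_params(fragment_length = config$fragment_length,
                                      overlap = config$overlap,
                                      min_orf_residues = config$min_orf_residues)
    lists <- lapply(groupset$groups, `[[`, "peptide_list")
    genomes <- read_genome_fasta(config$genome)
    hits <- do.call(rbind, lapply(seq_len(nrow(genomes)), function(i) {
      h <- scan_genome(genomes[i, ], lists, scan_params, config$min_score)
      attr(h, "scores") <- NULL
      h
    }))
    emit("genome_hits.tsv", hits)
    write_hits_bed(hits, file.path(config$out_dir, "genome_hits.bed"))
    outputs[["genome_hits.bed"]] <- sum(hits$status == "assigned")
  }

  write_run_config(config, file.path(config$out_dir, "config.yaml"))
  manifest <- data.frame(file = names(outputs),
                         rows = as.integer(unlist(outputs)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  write_table(manifest, file.path(config$out_dir, "manifest.tsv"))
  stage("done")
  invisible(list(groupset = groupset, records = records, hits = hits,
                 manifest = manifest))
}
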
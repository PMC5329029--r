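test_that("protein annotation assigns the unique best group above threshold", {
  withr::local_seed(61)
  peps_a <- unique(replicate(30, random_protein(6)))
  peps_b <- unique(replicate(30, random_protein(6)))
  peps_b <- setdiff(peps_b, peps_a)
  lists <- list(make_plist(peps_a, 1L), make_plist(peps_b, 2L))

  seq_a <- paste(c(peps_a[1:12], peps_b[1:3]), collapse = "")   # {A:>=12, B:>=3}
  seq_low <- paste(c(peps_a[1:4], "GGGGGG", peps_b[1:4]), collapse = "")
  seq_tie <- paste(c(peps_a[1:7], "GGGGGG", peps_b[1:7]), collapse = "")
  rec <- make_records(c(seq_a, seq_low, seq_tie))

  ann <- annotate_proteins(rec, lists, min_score = 5)
  a <- ann$assignments
  expect_equal(a$status, c("assigned", "unassigned", "ambiguous"))
  expect_equal(a$best_group[1], 1L)
  expect_gte(a$score[1], 12)
  expect_true(all(is.na(a$best_group[2:3])))
  # scores equal the independent distinct-substring oracle
  for (i in seq_len(nrow(rec))) {
    expect_equal(unname(ann$scores[i, "1"]),
                 oracle_score(rec$sequence[i], peps_a))
    expect_equal(unname(ann$scores[i, "2"]),
                 oracle_score(rec$sequence[i], peps_b))
  }
  expect_error(annotate_proteins(rec, list(make_plist("AAAAAA", 1L),
                                           make_plist("CCCCCC", 1L))),
               "duplicate group ids")
})

test_that("genome fragmentation follows the 2000/100 stepping rule", {
  p <- genome_scan_params()
  f1 <- fragment_genome(random_dna_record(3900), p)
  expect_equal(f1$offset, c(0L, 1900L))
  expect_equal(nchar(f1$sequence), c(2000L, 2000L))
  f2 <- fragment_genome(random_dna_record(1500), p)
  expect_equal(f2$offset, 0L)
  expect_equal(nchar(f2$sequence), 1500L)
  f3 <- fragment_genome(random_dna_record(4000), p)
  expect_equal(f3$offset, c(0L, 1900L, 3800L))
  expect_equal(nchar(f3$sequence), c(2000L, 2000L, 200L))
  # every base covered by at least one fragment
  for (f in list(f1, f2, f3)) {
    cov <- rep(FALSE, max(f$offset + nchar(f$sequence)))
    for (i in seq_len(nrow(f))) {
      cov[(f$offset[i] + 1):(f$offset[i] + nchar(f$sequence[i]))] <- TRUE
    }
    expect_true(all(cov))
  }
})

test_that("six-frame extraction keeps stop-free segments above the length cut", {
  withr::local_seed(62)
  pep60 <- random_protein(60)
  cds <- reverse_translate_fixture(pep60)
  frag <- list(offset = 0L, sequence = paste0("TAA", cds, "TAA"))
  hits <- six_frame_orfs(as.data.frame(frag), genome_scan_params(), "g")
  fwd0 <- hits[hits$strand == "+" & hits$frame == 0, ]
  expect_equal(nrow(fwd0), 1)
  expect_equal(fwd0$peptide, pep60)
  expect_equal(fwd0$length_aa, 60L)
  expect_equal(c(fwd0$genome_start, fwd0$genome_end), c(3L, 183L))

  # 51 residues kept, 50 dropped
  for (n in c(50, 51)) {
    pep <- random_protein(n)
    frag <- list(offset = 0L,
                 sequence = paste0("TAA", reverse_translate_fixture(pep), "TAA"))
    hits <- six_frame_orfs(as.data.frame(frag), genome_scan_params(), "g")
    expect_equal(pep %in% hits$peptide, n >= 51)
  }

  all_stops <- list(offset = 0L, sequence = strrep("TAA", 50))
  expect_equal(nrow(six_frame_orfs(as.data.frame(all_stops),
                                   genome_scan_params(), "g")), 0)
})

test_that("edge segments without a terminating stop are kept", {
  withr::local_seed(63)
  pep <- random_protein(55)
  frag <- list(offset = 0L, sequence = reverse_translate_fixture(pep))
  hits <- six_frame_orfs(as.data.frame(frag), genome_scan_params(), "g")
  expect_true(pep %in% hits$peptide)
})

test_that("genome scan finds a minus-strand planted gene at its coordinates", {
  fam <- generate_families(family_spec(n_groups = 1, members_per_group = 10,
                                       seed = 64))
  gs <- ppr_cluster(fam$records, ppr_params())
  lists <- lapply(gs$groups, `[[`, "peptide_list")
  # force the gene onto the minus strand by regenerating until truth says so
  for (s in 1:10) {
    g <- generate_genome(data.frame(peptide = fam$records$sequence[1],
                                    group = 1L), 400, seed = 6400 + s)
    if (g$truth$strand[1] == "-") break
  }
  expect_equal(g$truth$strand[1], "-")
  hits <- scan_genome(g$genome, lists, genome_scan_params(), 5)
  ok <- hits$status == "assigned" & hits$strand == "-" &
    hits$genome_start < g$truth$end[1] & hits$genome_end > g$truth$start[1]
  expect_true(any(ok))
  expect_true(all(hits$best_group[ok] == 1L))

  rescan <- scan_genome(g$genome, lists, genome_scan_params(), 5)
  expect_identical(hits, rescan)
})

test_that("scanned coordinates round-trip through retranslation", {
  fam <- generate_families(family_spec(n_groups = 2, members_per_group = 8,
                                       seed = 65))
  g <- generate_genome(data.frame(peptide = fam$records$sequence[1:4],
                                  group = c(1L, 1L, 2L, 2L)),
                       700, seed = 66)
  hits <- scan_genome(g$genome, list(make_plist("AAAAAA", 1L)),
                      genome_scan_params(), 5)
  for (i in seq_len(nrow(hits))) {
    nt <- substr(g$genome$sequence, hits$genome_start[i] + 1,
                 hits$genome_end[i])
    if (hits$strand[i] == "-") nt <- oracle_revcomp(nt)
    expect_equal(oracle_translate(nt), hits$peptide[i])
  }
})

test_that("per-class summaries average assigned counts", {
  ann_n <- function(n, group = 1L) {
    data.frame(id = seq_len(max(n, 1)),
               best_group = group,
               score = 10L,
               status = c(rep("assigned", n),
                          rep("unassigned", max(n, 1) - n)),
               stringsAsFactors = FALSE)
  }
  out <- summarize_by_class(
    organisms = sprintf("org%d", 1:4),
    classes = rep("coprophilic", 4),
    annotations = lapply(c(4, 4, 4, 4), ann_n))
  expect_equal(out$mean_count[out$group == "all"], 4)

  out2 <- summarize_by_class(
    organisms = sprintf("org%d", 1:4),
    classes = rep("white_rot", 4),
    annotations = lapply(c(1, 0, 2, 1), ann_n))
  expect_equal(out2$mean_count[out2$group == "all"], 1)

  expect_error(summarize_by_class(organisms = "o", classes = NA_character_,
                                  annotations = list(ann_n(1))),
               "class label")
})

test_that("BED export keeps assigned hits with capped scores", {
  hits <- data.frame(genome_id = "g", fragment_offset = 0L,
                     strand = c("+", "-"), frame = 0L,
                     peptide = c("AAA", "CCC"), length_aa = 3L,
                     genome_start = c(10L, 50L), genome_end = c(19L, 59L),
                     best_group = c(1L, NA), score = c(7L, 2L),
                     status = c("assigned", "unassigned"),
                     stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".bed")
  write_hits_bed(hits, path)
  lines <- readLines(path)
  expect_length(lines, 1)
  expect_equal(strsplit(lines, "\t")[[1]],
               c("g", "10", "19", "group1", "7", "+"))
})
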
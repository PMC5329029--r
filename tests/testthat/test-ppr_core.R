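test_that("peptide windows are enumerated with 1-based starts, X excluded", {
  w <- extract_peptides("MKTAYIA", 6)
  expect_equal(w$peptide, c("MKTAYI", "KTAYIA"))
  expect_equal(w$start, c(1L, 2L))
  expect_equal(nrow(extract_peptides("MKXTAYIA", 6)), 0)
  expect_equal(extract_peptides("AAAAAA", 6),
               data.frame(peptide = "AAAAAA", start = 1L,
                          stringsAsFactors = FALSE))
  expect_equal(nrow(extract_peptides("MKT", 6)), 0)
})

test_that("peptide frequency counts protein presence, not occurrences", {
  rec <- make_records(c(plant_peptide("GHSYAG", 10, len = 40, filler = "P"),
                        plant_peptide("GHSYAG", 25, len = 40, filler = "P")))
  freq <- peptide_protein_frequency(rec, 6)
  expect_equal(unname(freq[["GHSYAG"]]), 2L)
  twice <- make_records(paste0("AAAAAA", "PPPPPP", "AAAAAA"))
  expect_equal(unname(peptide_protein_frequency(twice, 6)[["AAAAAA"]]), 1L)
  withr::local_seed(21)
  disjoint <- make_records(c(strrep("AC", 10), strrep("DE", 10)))
  expect_true(all(peptide_protein_frequency(disjoint, 6) == 1L))
})

test_that("peptide lists take the top-frequency peptides with lexicographic ties", {
  withr::local_seed(22)
  seq75 <- random_protein(75)
  rec <- make_records(rep(seq75, 20))
  pl <- derive_peptide_list(rec, ppr_params())
  expect_equal(length(pl$peptides), 70)
  expect_setequal(pl$peptides, unique(extract_peptides(seq75, 6)$peptide))
  expect_true(all(pl$frequency == 20))

  few <- make_records(rep("AAAAAACCCCC", 3))  # 6 distinct windows only
  pl2 <- derive_peptide_list(few, ppr_params())
  expect_equal(length(pl2$peptides), 6)

  # equal frequencies at the cap boundary: lexicographically smaller kept
  tie <- make_records(c("CCCCCC", "AAAAAA"))
  p_tie <- ppr_params(peptides_per_protein = 1, peptides_per_group = 1,
                      min_group_size = 1)
  pl3 <- derive_peptide_list(tie, p_tie)
  expect_equal(pl3$peptides, "AAAAAA")
})

test_that("protein scoring counts distinct list peptides once each", {
  withr::local_seed(23)
  peps <- unique(replicate(70, random_protein(6)))
  pl <- make_plist(peps)
  seq3 <- paste0(strrep("G", 30), peps[1], strrep("G", 10), peps[5],
                 peps[9], strrep("G", 30))
  expect_equal(score_protein(seq3, pl), oracle_score(seq3, peps))
  expect_equal(score_protein(seq3, pl), 3L)
  expect_equal(score_protein(strrep("G", 100), pl), 0L)
  concat <- paste(peps, collapse = "")
  expect_equal(score_protein(concat, pl), length(peps))
})

test_that("form_group recovers a planted family from background noise", {
  withr::local_seed(24)
  fam <- generate_families(family_spec(n_groups = 1, members_per_group = 20,
                                       seed = 101))
  bg <- make_records(replicate(10, random_protein(300)),
                     ids = sprintf("bg%d", 1:10))
  working <- rbind(fam$records, bg)
  res <- form_group(working, ppr_params(), 1L)
  expect_setequal(res$group$members, fam$records$id)
  expect_setequal(res$remaining$id, bg$id)
  # membership contract against the independent oracle
  for (m in res$group$members) {
    s <- working$sequence[working$id == m]
    expect_gte(oracle_score(s, res$group$peptide_list$peptides), 10)
  }
})

test_that("form_group refuses groups below the minimum size", {
  one <- make_records(strrep("ACDEFG", 20))
  res <- form_group(one, ppr_params(), 1L)
  expect_null(res$group)
  expect_equal(res$remaining$id, one$id)
})

test_that("the first group formed is seeded by the winning top peptide", {
  # two disjoint two-member families; equal peptide frequencies, so the
  # lexicographically smallest most-frequent peptide decides which family
  # seeds group 1
  fam_a <- make_records(rep(plant_peptide("CDEFGH", 3, len = 60, filler = "A"), 2),
                        ids = c("a1", "a2"))
  fam_b <- make_records(rep(plant_peptide("WYVWYV", 3, len = 60, filler = "T"), 2),
                        ids = c("b1", "b2"))
  working <- rbind(fam_b, fam_a)  # input order does not decide the seed
  params <- ppr_params(peptides_per_protein = 5, peptides_per_group = 70)
  freq <- peptide_protein_frequency(working, 6)
  top <- sort(names(freq)[freq == max(freq)])[1]
  res <- form_group(working, params, 1L)
  expect_true(grepl(top, working$sequence[working$id %in% res$group$members][1],
                    fixed = TRUE))
  expect_setequal(res$group$members,
                  working$id[grepl(top, working$sequence, fixed = TRUE)])
})

test_that("clustering partitions the input deterministically", {
  for (seed in c(31, 32, 33)) {
    fam <- generate_families(family_spec(seed = seed))
    withr::with_seed(seed, {
      bg <- make_records(replicate(5, random_protein(300)),
                         ids = sprintf("bg%d", 1:5))
    })
    recs <- rbind(fam$records, bg)
    gs <- ppr_cluster(recs, ppr_params())
    assigned <- unlist(lapply(gs$groups, `[[`, "members"))
    expect_setequal(c(assigned, gs$unclassified), recs$id)
    expect_equal(length(c(assigned, gs$unclassified)), nrow(recs))
    gs2 <- ppr_cluster(recs, ppr_params())
    expect_identical(membership_table(gs), membership_table(gs2))
  }
})

test_that("degenerate inputs cluster as specified", {
  same <- make_records(rep(strrep("ACDEFGHIKLMNPQ", 6), 10))
  gs <- ppr_cluster(same, ppr_params())
  expect_length(gs$groups, 1)
  expect_setequal(gs$groups[[1]]$members, same$id)

  tiny <- make_records(c("MKT", "ACD", "EFG"))
  gs2 <- ppr_cluster(tiny, ppr_params())
  expect_length(gs2$groups, 0)
  expect_setequal(gs2$unclassified, tiny$id)

  expect_error(ppr_cluster(make_records(c("AAA", "CCC"), ids = c("a", "a"))),
               "unique")
})

test_that("a protein sharing no group peptide never changes membership", {
  spec <- family_spec(n_groups = 2, members_per_group = 10, seed = 41,
                      alphabet = setdiff(c("A","C","D","E","F","G","H","I","K",
                                           "L","M","N","Q","R","S","T","V","W",
                                           "Y"), "P"))
  fam <- generate_families(spec)
  gs_before <- ppr_cluster(fam$records, ppr_params())
  inert <- make_records(strrep("P", 300), ids = "inert")
  gs_after <- ppr_cluster(rbind(fam$records, inert), ppr_params())
  expect_equal(lapply(gs_before$groups, `[[`, "members"),
               lapply(gs_after$groups, `[[`, "members"))
  expect_true("inert" %in% gs_after$unclassified)
})

test_that("peptide list tables round-trip through their TSV layout", {
  fam <- generate_families(family_spec(n_groups = 2, members_per_group = 5,
                                       seed = 51))
  gs <- ppr_cluster(fam$records, ppr_params())
  tab <- peptide_list_table(gs)
  expect_equal(names(tab), c("group_id", "rank", "peptide", "protein_frequency"))
  back <- peptide_lists_from_table(tab)
  orig <- lapply(gs$groups, `[[`, "peptide_list")
  expect_equal(lapply(back, `[[`, "peptides"), lapply(orig, `[[`, "peptides"))
  expect_equal(lapply(back, `[[`, "frequency"), lapply(orig, `[[`, "frequency"))
})
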
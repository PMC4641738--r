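test_that("identical proteins form one cluster; representative id rule holds", {
  prot <- data.frame(
    protein_id = c("b_prot", "a_prot"),
    aa_sequence = strrep("MKWVLEADGHIRFYPQNCST", 2),  # twice, identical 40-mers
    cog_id = "COG0001", categories = "C", stringsAsFactors = FALSE)
  cls <- cluster_category(prot, 0.6, fix_scheme)
  expect_length(cls, 1L)
  expect_setequal(cls[[1]]$member_ids, c("a_prot", "b_prot"))
  expect_equal(cls[[1]]$representative_id, "a_prot")
})

test_that("proteins sharing no identity form singleton clusters", {
  prot <- data.frame(
    protein_id = c("polyK", "polyD"),
    aa_sequence = c(strrep("K", 30), strrep("D", 30)),
    cog_id = c("COG0001", "COG0002"), categories = "C",
    stringsAsFactors = FALSE)
  cls <- cluster_category(prot, 0.6, fix_scheme)
  expect_length(cls, 2L)
  expect_error(cluster_category(prot, 1.2, fix_scheme), "identity_threshold")
  expect_equal(cluster_category(prot[0, ], 0.6, fix_scheme), list())
})

test_that("two tight families are recovered, agreeing with oracle single-linkage", {
  set.seed(101)
  fam1 <- random_peptide(50)
  fam2 <- random_peptide(50)
  seqs <- c(fam1, mutate_peptide(fam1, 0.1), mutate_peptide(fam1, 0.1),
            fam2, mutate_peptide(fam2, 0.1), mutate_peptide(fam2, 0.1))
  prot <- data.frame(protein_id = sprintf("q%d", 1:6), aa_sequence = seqs,
                     cog_id = "COG0001", categories = "C",
                     stringsAsFactors = FALSE)
  cls <- cluster_category(prot, 0.6, fix_scheme)
  got <- lapply(cls, `[[`, "member_ids")
  expect_length(got, 2L)
  expect_setequal(got[[which(vapply(got, function(g) "q1" %in% g, NA))]],
                  c("q1", "q2", "q3"))

  # oracle: all-pairs identity matrix + single-linkage at the threshold
  idm <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    al <- oracle_local_align(seqs[i], seqs[j], fix_scheme)
    idm[i, j] <- al$matches / min(nchar(seqs[i]), nchar(seqs[j]))
  }
  comp <- seq_len(6)
  for (i in 1:6) for (j in 1:6) {
    if (idm[i, j] >= 0.6) comp[comp == comp[j]] <- comp[i]
  }
  oracle_parts <- split(prot$protein_id, comp)
  expect_setequal(lapply(got, sort), lapply(unname(oracle_parts), sort))
})

test_that("clustering is independent of input row order", {
  prot <- fix_toy$db$proteins[fix_toy$db$proteins$categories == "J", ]
  cls1 <- cluster_category(prot, 0.6, fix_scheme)
  set.seed(3)
  cls2 <- cluster_category(prot[sample(nrow(prot)), ], 0.6, fix_scheme)
  expect_equal(cls1, cls2)
})

test_that("reduced database shrinks, conserves categories, records provenance", {
  red <- build_reduced_db(fix_toy$db, 0.6, fix_scheme)
  expect_equal(red$kind, "reduced")
  expect_lte(nrow(red$proteins), nrow(fix_toy$db$proteins))
  expect_equal(sort(unique(unlist(strsplit(red$proteins$categories, "")))),
               sort(unique(unlist(strsplit(fix_toy$db$proteins$categories, "")))))
  # provenance partitions each category's protein set
  for (cc in unique(red$provenance$category)) {
    members <- red$provenance$member_id[red$provenance$category == cc]
    in_cat <- fix_toy$db$proteins$protein_id[
      grepl(cc, fix_toy$db$proteins$categories, fixed = TRUE)]
    expect_setequal(members, in_cat)
    expect_false(anyDuplicated(members) > 0)
  }
  # each synthetic COG's 3 similar members collapse to one representative
  expect_equal(nrow(red$proteins), length(unique(fix_toy$db$proteins$cog_id)))
})

test_that("a database of mutually unrelated proteins reduces to itself", {
  set.seed(55)
  prot <- data.frame(protein_id = sprintf("u%d", 1:8),
                     aa_sequence = vapply(1:8, function(i) random_peptide(60), ""),
                     cog_id = sprintf("COG%04d", 1:8),
                     categories = rep(c("C", "E"), 4), stringsAsFactors = FALSE)
  full <- cog_database(prot)
  red <- build_reduced_db(full, 0.6, fix_scheme)
  expect_setequal(red$proteins$protein_id, prot$protein_id)
  expect_equal(red$proteins[order(red$proteins$protein_id), ],
               prot[order(prot$protein_id), ], ignore_attr = TRUE)
})

test_that("multi-category proteins appear in every matching partition", {
  parts <- partition_by_category(fix_mini_db)
  expect_setequal(names(parts), c("C", "E", "J"))
  expect_setequal(parts$C$protein_id, c("p1", "p2"))
  expect_equal(parts$E$protein_id, "p2")
  expect_equal(parts$J$protein_id, "p3")
  # union of partitions covers the database
  expect_setequal(unique(unlist(lapply(parts, `[[`, "protein_id"))),
                  fix_mini_db$proteins$protein_id)
})

test_that("a 25-category database yields exactly 25 non-empty partitions", {
  cfg <- simulation_config(n_categories = 25L, cogs_per_category = 1L,
                           proteins_per_cog = 1L, protein_length = 30L, seed = 7L)
  toy <- generate_toy_cogdb(cfg)
  parts <- partition_by_category(toy$db)
  expect_length(parts, 25L)
  expect_true(all(vapply(parts, nrow, 0L) > 0))
  expect_setequal(names(parts), category_alphabet())
})

test_that("database construction enforces record invariants", {
  bad <- fix_mini_db$proteins
  bad$categories[1] <- "5"
  expect_error(cog_database(bad), "category")
  dup <- fix_mini_db$proteins
  dup$protein_id[2] <- "p1"
  expect_error(cog_database(dup), "p1")
  expect_error(build_reduced_db(build_reduced_db(fix_toy$db, 0.6, fix_scheme)),
               "full")
})
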
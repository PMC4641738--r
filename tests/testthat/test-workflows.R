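opt1 <- annotate_reads(fix_reads$reads, fix_toy$db, fix_toy$xmap, option = 1)
red_db <- build_reduced_db(fix_toy$db, 0.6, fix_scheme)
opt3 <- annotate_reads(fix_reads$reads, fix_toy$db, fix_toy$xmap, option = 3,
                       reduced_db = red_db)

test_that("option 1 recovers planted truth and derives mapped namespaces", {
  expect_equal(opt1$assignments$cog_id, fix_reads$truth$source_cog_id)
  expect_equal(opt1$annotations$read_id, fix_reads$reads$read_id)
  i <- 1L
  cog <- opt1$assignments$cog_id[i]
  no <- as.integer(sub("COG", "", cog))
  expect_equal(opt1$annotations$kegg[i], sprintf("K%05d", no))
  expect_equal(opt1$annotations$seed[i], sprintf("SS%04d", no))
})

test_that("reads without a sub-threshold hit yield all-empty records", {
  rnd <- random_reads(2, 90, seed = 13)
  res <- annotate_reads(rnd, fix_toy$db, fix_toy$xmap, option = 1)
  expect_true(all(is.na(res$assignments$cog_id)))
  expect_true(all(res$annotations[, -1] == ""))
})

test_that("directed search recovers representative-resident reads like option 1", {
  # reads whose option-1 winner shares a category with the stage-1 winner
  # must get the same final COG (conditional option-equivalence)
  a1 <- opt1$assignments
  a3 <- opt3$assignments
  for (i in seq_len(nrow(a1))) {
    if (is.na(a1$cog_id[i]) || is.na(a3$stage1_category[i])) next
    shared <- length(intersect(strsplit(a1$category[i], "")[[1]],
                               strsplit(a3$stage1_category[i], "")[[1]])) > 0
    if (shared) expect_equal(a3$cog_id[i], a1$cog_id[i])
  }
  # on this fixture every read is planted, so options agree everywhere
  expect_equal(a3$cog_id, a1$cog_id)
})

test_that("a random read misses stage 1 and is reported unassigned", {
  rnd <- random_reads(1, 90, seed = 21)
  parts <- partition_by_category(fix_toy$db)
  da <- directed_assign(rnd[1, ], red_db, parts, search_config(), fix_scheme)
  expect_true(is.na(da$stage1_category))
  expect_null(da$best_hit)
  expect_error(directed_assign(rnd[1, ], red_db, list(), search_config()),
               "empty")
})

test_that("stage-2 search space is restricted to the stage-1 category", {
  parts <- partition_by_category(fix_toy$db)
  i <- 1L
  da <- directed_assign(fix_reads$reads[i, ], red_db, parts,
                        search_config(), fix_scheme)
  expect_false(is.null(da$best_hit))
  final_cat <- fix_toy$db$proteins$categories[
    fix_toy$db$proteins$protein_id == da$best_hit$subject_id]
  expect_true(any(strsplit(final_cat, "")[[1]] %in%
                    strsplit(da$stage1_category, "")[[1]]))
})

test_that("options 3/4 require a reduced database; engine follows the option", {
  expect_error(annotate_reads(fix_reads$reads, fix_toy$db, fix_toy$xmap,
                              option = 3), "reduced")
  expect_error(annotate_reads(fix_reads$reads, fix_toy$db, fix_toy$xmap,
                              option = 5), "option")
  opt2 <- annotate_reads(fix_reads$reads[1:8, ], fix_toy$db, fix_toy$xmap,
                         option = 2)
  # heuristic single-pass hits agree with exact on planted reads
  expect_equal(opt2$assignments$cog_id, opt1$assignments$cog_id[1:8])
})

test_that("the mapping phase is option-independent for fixed assignments", {
  rec1 <- transfer_annotations(opt1$assignments, fix_toy$xmap)
  rec3 <- transfer_annotations(opt3$assignments[, names(opt1$assignments)],
                               fix_toy$xmap)
  same <- opt1$assignments$cog_id == opt3$assignments$cog_id
  expect_equal(rec1[same, ], rec3[same, ], ignore_attr = TRUE)
})

test_that("external hit tables drive option-1 assignment", {
  hits <- data.frame(
    query_id = c("r1", "r1", "r2"),
    subject_id = c(fix_toy$db$proteins$protein_id[1],
                   fix_toy$db$proteins$protein_id[4],
                   "not_in_db"),
    percent_identity = 99, alignment_length = 30, mismatches = 0,
    gap_opens = 0, q_start = 1, q_end = 90, s_start = 1, s_end = 30,
    evalue = c(1e-20, 1e-10, 1e-30), bit_score = c(80, 50, 90),
    stringsAsFactors = FALSE)
  reads <- data.frame(read_id = c("r1", "r2"), nt_sequence = strrep("A", 90),
                      quality = NA_character_)
  res <- annotate_reads(reads, fix_toy$db, fix_toy$xmap, option = 1,
                        external_hits = hits)
  expect_equal(res$assignments$cog_id[1], fix_toy$db$proteins$cog_id[1])
  expect_true(is.na(res$assignments$cog_id[2]))  # unknown subject ignored
  expect_error(annotate_reads(reads, fix_toy$db, fix_toy$xmap, option = 3,
                              reduced_db = red_db, external_hits = hits),
               "single-pass")
})

test_that("functional profiles count multi-label reads once per term", {
  recs <- empty_annotation_records(c("r1", "r2", "r3", "r4"))
  recs$kegg <- c("K00001", "K00001", "K00002", "")
  recs$go[1] <- "GO:1;GO:2"
  prof <- build_profile(recs)
  expect_equal(prof$counts$kegg, c(K00001 = 2L, K00002 = 1L))
  expect_equal(prof$counts$go, c("GO:1" = 1L, "GO:2" = 1L))
  expect_equal(prof$n_reads_total, 4L)
  expect_equal(prof$n_reads_assigned[["kegg"]], 3L)

  empty <- build_profile(empty_annotation_records())
  expect_equal(empty$n_reads_total, 0L)
  expect_length(empty$counts$cog, 0L)

  path <- tempfile(fileext = ".tsv")
  write_profile(prof, path)
  back <- read_profile(path)
  expect_equal(back$kegg, prof$counts$kegg)
})
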
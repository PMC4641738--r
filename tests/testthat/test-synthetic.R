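test_that("generator counts follow the configuration arithmetic", {
  toy <- generate_toy_cogdb(simulation_config(seed = 7))
  expect_equal(nrow(toy$db$proteins), 25L * 2L * 3L)
  expect_equal(length(unique(toy$db$proteins$cog_id)), 50L)
  expect_setequal(unique(toy$db$proteins$categories), category_alphabet())
  # bijective truth crossmap: one term per namespace per COG
  e <- toy$xmap$entries
  expect_equal(nrow(e), 50L * 4L)
  expect_false(any(duplicated(e[, c("namespace", "term_id")])))
})

test_that("generation is a pure function of the configuration", {
  cfg <- simulation_config(n_categories = 3, seed = 123)
  a <- generate_toy_cogdb(cfg)
  b <- generate_toy_cogdb(cfg)
  expect_identical(a$db$proteins, b$db$proteins)
  expect_identical(a$xmap$entries, b$xmap$entries)
  ra <- sample_reads(a$db, cfg)
  rb <- sample_reads(b$db, cfg)
  expect_identical(ra$reads, rb$reads)
  expect_identical(ra$truth, rb$truth)
  # serialized forms are byte-identical
  f1 <- tempfile(); f2 <- tempfile()
  write_tagged_fasta(a$db, f1); write_tagged_fasta(b$db, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("zero substitution rate makes all COG members identical", {
  cfg <- simulation_config(n_categories = 2, intra_cog_substitution_rate = 0,
                           seed = 5)
  toy <- generate_toy_cogdb(cfg)
  for (g in split(toy$db$proteins$aa_sequence, toy$db$proteins$cog_id)) {
    expect_length(unique(g), 1L)
  }
})

test_that("read sampling respects counts, provenance and the error model", {
  expect_equal(nrow(fix_reads$reads), fix_cfg$n_reads)
  expect_equal(nrow(fix_reads$truth), fix_cfg$n_reads)
  expect_true(all(nchar(fix_reads$reads$nt_sequence) == fix_cfg$read_length_nt))
  expect_true(all(fix_reads$truth$nt_errors_introduced == 0L))
  expect_true(all(fix_reads$truth$source_protein_id %in%
                    fix_toy$db$proteins$protein_id))
  expect_setequal(unique(fix_reads$truth$strand), c("+", "-"))
})

test_that("error-free forward reads translate verbatim into their source", {
  cfg <- simulation_config(n_categories = 2, protein_length = 60,
                           n_reads = 10, read_length_nt = 90,
                           nt_error_rate = 0, revcomp_probability = 0,
                           seed = 31)
  toy <- generate_toy_cogdb(cfg)
  rt <- sample_reads(toy$db, cfg)
  for (i in seq_len(10)) {
    pep <- six_frame_translate(rt$reads$nt_sequence[i])[["+1"]]
    src <- toy$db$proteins$aa_sequence[
      toy$db$proteins$protein_id == rt$truth$source_protein_id[i]]
    expect_true(grepl(pep, src, fixed = TRUE))
  }
})

test_that("reads longer than the proteins allow are rejected", {
  cfg_bad <- simulation_config(n_categories = 1, protein_length = 20,
                               read_length_nt = 90, seed = 1)
  toy <- generate_toy_cogdb(cfg_bad)
  expect_error(sample_reads(toy$db, cfg_bad), "at least")
  expect_error(simulation_config(nt_error_rate = 1.5), "rates")
  expect_error(simulation_config(n_categories = 26), "n_categories")
})

test_that("option-1 annotation accuracy equals the exhaustive oracle's", {
  reads <- fix_reads$reads[1:6, ]
  res <- annotate_reads(reads, fix_toy$db, fix_toy$xmap, option = 1)
  prot <- fix_toy$db$proteins
  oracle_cogs <- vapply(reads$nt_sequence, function(nt) {
    hit <- oracle_best_hit(nt, fix_toy$db, fix_scheme)
    if (is.null(hit)) NA_character_
    else prot$cog_id[prot$protein_id == hit$subject_id]
  }, "", USE.NAMES = FALSE)
  truth <- fix_reads$truth$source_cog_id[1:6]
  expect_equal(mean(res$assignments$cog_id[1:6] == truth),
               mean(oracle_cogs == truth))
  expect_equal(res$assignments$cog_id[1:6], oracle_cogs)
})
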
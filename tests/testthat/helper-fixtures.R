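# Shared small fixtures, generated in code (no files). The 5-category toy
# database keeps per-test search cost low; category coverage tests build
# their own 25-category database.

fix_scheme <- scoring_scheme()

fix_cfg <- simulation_config(
  n_categories = 5L, cogs_per_category = 2L, proteins_per_cog = 3L,
  protein_length = 60L, n_reads = 30L, read_length_nt = 90L,
  nt_error_rate = 0, revcomp_probability = 0.5, seed = 7L)

fix_toy <- generate_toy_cogdb(fix_cfg)
fix_reads <- sample_reads(fix_toy$db, fix_cfg)

# a tiny hand-built database with known tags (covers multi-category proteins)
fix_mini_db <- cog_database(data.frame(
  protein_id = c("p1", "p2", "p3"),
  aa_sequence = c(strrep("MKWVLE", 10), strrep("ADGHIR", 10), strrep("FYPQNC", 10)),
  cog_id = c("COG9001", "COG9002", "COG9003"),
  categories = c("C", "CE", "J"),
  stringsAsFactors = FALSE))

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
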
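mk_rows <- function(...) {
  do.call(rbind, lapply(list(...), function(x) {
    data.frame(cog_id = x[1], namespace = x[2], term_id = x[3], source = x[4],
               stringsAsFactors = FALSE)
  }))
}

test_that("homology-derived mappings win conflicts and conflicts are logged", {
  rows <- mk_rows(c("COG0001", "KEGG", "K00001", "curated_import"),
                  c("COG0001", "KEGG", "K00002", "homology"),
                  c("COG0002", "KEGG", "K00010", "curated_import"))
  xm <- build_crossmap(rows)
  e <- xm$entries
  expect_equal(e$term_id[e$cog_id == "COG0001" & e$namespace == "KEGG"], "K00002")
  expect_equal(e$term_id[e$cog_id == "COG0002"], "K00010")
  expect_equal(nrow(xm$conflict_log), 1L)
  expect_equal(xm$conflict_log$discarded, "K00001")
  expect_equal(xm$conflict_log$kept, "K00002")
})

test_that("agreeing sources merge without a conflict entry", {
  rows <- mk_rows(c("COG0003", "SEED", "SS1", "curated_import"),
                  c("COG0003", "SEED", "SS1", "homology"))
  xm <- build_crossmap(rows)
  expect_equal(xm$entries$term_id, "SS1")
  expect_equal(nrow(xm$conflict_log), 0L)
})

test_that("GO terms arrive by composition through the kept Pfam set", {
  rows <- mk_rows(c("COG0003", "PFAM", "PF00001", "curated_import"))
  p2g <- data.frame(pfam_id = "PF00001", go_id = "GO:0008270")
  xm <- build_crossmap(rows, p2g)
  e <- xm$entries
  expect_equal(e$term_id[e$namespace == "GO"], "GO:0008270")
  # composition respects conflict resolution: losing Pfam terms produce no GO
  rows2 <- rbind(rows, mk_rows(c("COG0003", "PFAM", "PF00099", "homology")))
  xm2 <- build_crossmap(rows2, p2g)
  expect_length(xm2$entries$term_id[xm2$entries$namespace == "GO"], 0L)
})

test_that("crossmap construction is independent of row order", {
  set.seed(8)
  rows <- mk_rows(c("COG0001", "KEGG", "K00001", "curated_import"),
                  c("COG0001", "KEGG", "K00002", "homology"),
                  c("COG0001", "PFAM", "PF00007", "homology"),
                  c("COG0002", "GO", "GO:0000001", "curated_import"),
                  c("COG0002", "SEED", "SS9", "homology"))
  p2g <- data.frame(pfam_id = "PF00007", go_id = "GO:0042222")
  xm1 <- build_crossmap(rows, p2g)
  xm2 <- build_crossmap(rows[sample(nrow(rows)), ], p2g)
  expect_equal(xm1$entries, xm2$entries)
  # precedence totality: every logged conflict keeps the homology set
  hom <- rows[rows$source == "homology", ]
  for (k in seq_len(nrow(xm1$conflict_log))) {
    cl <- xm1$conflict_log[k, ]
    expect_setequal(strsplit(cl$kept, ";")[[1]],
                    hom$term_id[hom$cog_id == cl$cog_id &
                                  hom$namespace == cl$namespace])
  }
  expect_error(build_crossmap(mk_rows(c("COG1", "BAD", "x", "homology"))),
               "namespace")
})

test_that("serialization round-trips the entries exactly", {
  path <- tempfile(fileext = ".tsv")
  write_crossmap(fix_toy$xmap, path)
  back <- read_crossmap(path)
  expect_equal(back$entries, fix_toy$xmap$entries)
})

test_that("pfam2go flat files parse the external2go dialect", {
  p <- write_lines_tmp(c(
    "!version date 2015/01/01",
    "Pfam:PF00001 7tm_1 > GO:G protein-coupled receptor activity ; GO:0004930",
    "Pfam:PF00002 7tm_2 > GO:integral component of membrane ; GO:0016021"))
  tab <- parse_pfam2go(p)
  expect_equal(tab$pfam_id, c("PF00001", "PF00002"))
  expect_equal(tab$go_id, c("GO:0004930", "GO:0016021"))
})

test_that("annotation transfer is pure lookup with defined fallbacks", {
  asg <- data.frame(read_id = c("r1", "r2", "r3"),
                    cog_id = c("COG0001", NA, "COG9999"),
                    category = c("J", NA, "C"), stringsAsFactors = FALSE)
  before <- alignment_call_count()
  rec <- transfer_annotations(asg, fix_toy$xmap)
  expect_equal(alignment_call_count(), before)  # zero alignment work
  expect_equal(rec$cog, c("COG0001", "", "COG9999"))
  expect_equal(rec$kegg, c("K00001", "", ""))  # unknown COG: namespaces empty
  expect_equal(rec$category, c("J", "", "C"))
  expect_equal(unname(unlist(rec[2, -1])), rep("", 6))
})
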
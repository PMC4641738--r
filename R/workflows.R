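#' Annotate reads with one of the four workflow options
#'
#' The homology-search phase assigns each read to the COG of its best
#' sub-threshold hit; the mapping phase (common to all options) derives the
#' KEGG, Pfam, GO and SEED namespaces from the cross-mapping store.
#'
#' * Option 1: single pass against the full database, exact engine.
#' * Option 2: single pass against the full database, heuristic engine.
#' * Option 3: two-stage directed search (stage 1 against the reduced
#'   representative database fixes a tentative category; stage 2 searches
#'   only that category's partition(s) of the full database), exact engine.
#' * Option 4: as option 3 with the heuristic engine.
#'
#' For options 1 and 2 a pre-computed tabular hit file from an external
#' aligner may replace the built-in engine (`external_hits`).
#'
#' @param reads Data frame from [read_sequences()].
#' @param full_db Full [cog_database()].
#' @param xmap A [build_crossmap()] store.
#' @param option Workflow option, 1-4.
#' @param reduced_db Reduced [cog_database()]; required for options 3/4.
#' @param config A [search_config()]; its `engine_mode` is overridden by
#'   the option (exact for 1/3, heuristic for 2/4).
#' @param scheme A [scoring_scheme()].
#' @param external_hits Optional data frame from [parse_external_hits()]
#'   (options 1/2 only).
#' @param fallback_full For options 3/4: re-search stage-2 misses against
#'   the full database (off by default, keeping the directed search's cost
#'   bounded).
#' @return List with `annotations` (one annotation record per read, input
#'   order) and `assignments` (data frame `read_id`, `cog_id`, `category`,
#'   `option`, `stage1_category`, `subject_id`, `frame`, `raw_score`,
#'   `bit_score`, `evalue`; `NA` where unassigned).
#' @export
annotate_reads <- function(reads, full_db, xmap, option = 1L,
                           reduced_db = NULL, config = search_config(),
                           scheme = scoring_scheme(), external_hits = NULL,
                           fallback_full = FALSE) {
  stopifnot(inherits(full_db, "cog_database"), inherits(xmap, "cog_crossmap"))
  option <- as.integer(option)
  if (!option %in% 1:4) stop("option must be 1, 2, 3 or 4")
  if (option %in% c(3L, 4L) && is.null(reduced_db)) {
    stop("options 3 and 4 require a reduced database")
  }
  if (!is.null(external_hits) && option %in% c(3L, 4L)) {
    stop("external hit tables are supported for the single-pass options 1 and 2 only")
  }
  config$engine_mode <- if (option %in% c(1L, 3L)) "exact" else "heuristic"

  n <- nrow(reads)
  asg <- data.frame(read_id = reads$read_id,
                    cog_id = NA_character_, category = NA_character_,
                    option = option, stage1_category = NA_character_,
                    subject_id = NA_character_, frame = NA_character_,
                    raw_score = NA_integer_, bit_score = NA_real_,
                    evalue = NA_real_, stringsAsFactors = FALSE)

  if (!is.null(external_hits)) {
    ext <- assign_from_external_hits(external_hits, full_db, config)
    m <- match(asg$read_id, ext$read_id)
    hit <- !is.na(m)
    for (col in c("cog_id", "category", "subject_id", "raw_score",
                  "bit_score", "evalue")) {
      asg[[col]][hit] <- ext[[col]][m[hit]]
    }
  } else if (option %in% c(1L, 2L)) {
    seed_index <- if (config$engine_mode == "heuristic") {
      build_seed_index(full_db, config$seed_word_length)
    } else NULL
    for (i in seq_len(n)) {
      hit <- search_read(reads[i, ], full_db, config, scheme, seed_index)
      asg[i, ] <- fill_assignment(asg[i, ], hit, full_db)
    }
  } else {
    partitions <- partition_by_category(full_db)
    stage1_index <- if (config$engine_mode == "heuristic") {
      build_seed_index(reduced_db, config$seed_word_length)
    } else NULL
    for (i in seq_len(n)) {
      da <- directed_assign(reads[i, ], reduced_db, partitions, config,
                            scheme, full_db = if (fallback_full) full_db,
                            stage1_index = stage1_index)
      asg$stage1_category[i] <- da$stage1_category
      asg[i, ] <- fill_assignment(asg[i, ], da$best_hit, full_db,
                                  stage1 = da$stage1_category)
    }
  }

  list(annotations = transfer_annotations(asg, xmap), assignments = asg)
}

fill_assignment <- function(row, hit, db, stage1 = row$stage1_category) {
  row$stage1_category <- stage1
  if (is.null(hit)) return(row)
  p <- db$proteins[db$proteins$protein_id == hit$subject_id, ]
  row$cog_id <- p$cog_id
  row$category <- p$categories
  row$subject_id <- hit$subject_id
  row$frame <- hit$frame
  row$raw_score <- hit$raw_score
  row$bit_score <- hit$bit_score
  row$evalue <- hit$evalue
  row
}

#' Two-stage directed COG assignment of one read
#'
#' Stage 1 searches the reduced representative database; the tag(s) of the
#' winning representative become the read's tentative category. Stage 2
#' searches only the union of the full-database partitions for those
#' categories and fixes the final COG call. A stage-1 miss leaves the read
#' unassigned (stage 2 is skipped); a stage-2 miss leaves it unassigned
#' with the tentative category recorded, unless `full_db` is supplied for
#' fallback to a full single-pass search.
#'
#' @param read One-row data frame with `read_id`, `nt_sequence`.
#' @param reduced_db Reduced [cog_database()].
#' @param partitions Category partitions of the originating full database,
#'   from [partition_by_category()]; must be non-empty.
#' @param config A [search_config()].
#' @param scheme A [scoring_scheme()].
#' @param full_db Optional full database enabling fallback on stage-2 miss.
#' @param stage1_index Optional heuristic seed index for the reduced
#'   database.
#' @return List with `read_id`, `stage1_category` (tag string or `NA`) and
#'   `best_hit` (final [search_read()] hit or `NULL`).
#' @export
directed_assign <- function(read, reduced_db, partitions,
                            config = search_config(),
                            scheme = scoring_scheme(), full_db = NULL,
                            stage1_index = NULL) {
  stopifnot(inherits(reduced_db, "cog_database"))
  if (length(partitions) == 0L) stop("partitions map is empty")
  out <- list(read_id = if (is.data.frame(read)) read$read_id[1L] else read$read_id,
              stage1_category = NA_character_, best_hit = NULL)
  s1 <- search_read(read, reduced_db, config, scheme, stage1_index)
  if (is.null(s1)) return(out)
  rep_row <- reduced_db$proteins[reduced_db$proteins$protein_id == s1$subject_id, ]
  out$stage1_category <- rep_row$categories
  cats <- strsplit(rep_row$categories, "")[[1]]
  cats <- cats[cats %in% names(partitions)]
  if (length(cats) == 0L) return(out)
  sub_prot <- unique(do.call(rbind, partitions[cats]))
  stage2_db <- cog_database(sub_prot, kind = "full")
  s2 <- search_read(read, stage2_db, config, scheme)
  if (is.null(s2) && !is.null(full_db)) {
    s2 <- search_read(read, full_db, config, scheme)
  }
  out$best_hit <- s2
  out
}

# Best external hit per query under the e-value threshold; ties by larger
# bit score, then lexicographic subject id. Subjects must exist in the
# database so the COG/category labels can be attached.
assign_from_external_hits <- function(hits, db, config) {
  hits <- hits[hits$evalue < config$evalue_threshold, , drop = FALSE]
  hits <- hits[hits$subject_id %in% db$proteins$protein_id, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(read_id = character(), cog_id = character(),
                      category = character(), subject_id = character(),
                      raw_score = integer(), bit_score = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  ord <- order(hits$query_id, hits$evalue, -hits$bit_score, hits$subject_id)
  hits <- hits[ord, ]
  best <- hits[!duplicated(hits$query_id), ]
  m <- match(best$subject_id, db$proteins$protein_id)
  data.frame(read_id = best$query_id,
             cog_id = db$proteins$cog_id[m],
             category = db$proteins$categories[m],
             subject_id = best$subject_id,
             raw_score = NA_integer_,
             bit_score = best$bit_score,
             evalue = best$evalue, stringsAsFactors = FALSE)
}

#' Count annotation terms across reads
#'
#' Builds a functional profile: per namespace, the number of reads carrying
#' each term (a read with k terms increments k counters by one each).
#' Unassigned reads contribute to `n_reads_total` only.
#'
#' @param records Annotation data frame (as from [annotate_reads()] or
#'   [read_annotation_table()]).
#' @return Object of class `"functional_profile"`: list with `counts`
#'   (named list namespace -> named integer vector), `n_reads_total`, and
#'   `n_reads_assigned` per namespace.
#' @examples
#' recs <- empty_annotation_records(c("r1", "r2"))
#' recs$kegg <- c("K00001", "K00001")
#' build_profile(recs)$counts$kegg  # K00001: 2
#' @export
build_profile <- function(records) {
  counts <- list()
  assigned <- integer()
  for (ns in annotation_namespaces()) {
    terms <- strsplit(records[[ns]], ";", fixed = TRUE)
    terms <- lapply(terms, function(v) v[nzchar(v)])
    assigned[[ns]] <- sum(lengths(terms) > 0L)
    tab <- table(unlist(terms))
    counts[[ns]] <- stats::setNames(as.integer(tab), names(tab))
  }
  structure(list(counts = counts, n_reads_total = nrow(records),
                 n_reads_assigned = assigned),
            class = "functional_profile")
}

#' @export
print.functional_profile <- function(x, ...) {
  cat("Functional profile over", x$n_reads_total, "reads\n")
  for (ns in names(x$counts)) {
    cat(sprintf("  %-9s %4d terms, %4d reads assigned\n", ns,
                length(x$counts[[ns]]), x$n_reads_assigned[[ns]]))
  }
  invisible(x)
}

#' Write a functional profile to TSV (namespace, term, count)
#' @param profile A [build_profile()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "functional_profile"))
  rows <- list()
  for (ns in names(profile$counts)) {
    v <- profile$counts[[ns]]
    if (length(v) == 0L) next
    rows[[ns]] <- data.frame(namespace = ns, term = names(v),
                             count = as.integer(v), stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows)
    else data.frame(namespace = character(), term = character(),
                    count = integer())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a functional profile TSV written by [write_profile()]
#' @param path Input path.
#' @return A named list namespace -> named integer count vector.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, colClasses = c("character", "character", "integer"))
  if (!identical(names(d), c("namespace", "term", "count"))) {
    stop("unexpected profile columns in ", path)
  }
  lapply(split(d, d$namespace), function(g) {
    stats::setNames(as.integer(g$count), g$term)
  })
}
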
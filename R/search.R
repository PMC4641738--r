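#' Search configuration for the translated homology engine
#'
#' @param evalue_threshold Accept a hit only if its e-value is strictly
#'   below this positive threshold. Default `1e-5`, the conventional
#'   cut-off for translated searches of short reads.
#' @param engine_mode `"exact"` (full Smith-Waterman of every frame against
#'   every subject), `"heuristic"` (shared k-peptide seed prefilter, then
#'   exact alignment of the surviving candidates; may miss hits but never
#'   invents or rescores one), or `"external"` (assignments taken from a
#'   pre-computed tabular hit file).
#' @param seed_word_length Seed k-mer length for heuristic mode (>= 2,
#'   default 4). Seeds containing `X` never match.
#' @param max_hits_retained Hits kept per read (default 1; every downstream
#'   rule uses only the best hit).
#' @return An object of class `"cog_search_config"`.
#' @export
search_config <- function(evalue_threshold = 1e-5,
                          engine_mode = c("exact", "heuristic", "external"),
                          seed_word_length = 4L, max_hits_retained = 1L) {
  engine_mode <- match.arg(engine_mode)
  if (!(evalue_threshold > 0)) stop("evalue_threshold must be positive")
  seed_word_length <- as.integer(seed_word_length)
  if (seed_word_length < 2L) stop("seed_word_length must be >= 2")
  max_hits_retained <- as.integer(max_hits_retained)
  if (max_hits_retained < 1L) stop("max_hits_retained must be >= 1")
  structure(list(evalue_threshold = evalue_threshold,
                 engine_mode = engine_mode,
                 seed_word_length = seed_word_length,
                 max_hits_retained = max_hits_retained),
            class = "cog_search_config")
}

peptide_kmers <- function(peptide, k) {
  n <- nchar(peptide)
  if (n < k) return(character())
  km <- substring(peptide, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  unique(km[!grepl("X", km, fixed = TRUE) & !grepl("*", km, fixed = TRUE)])
}

# k-mer -> integer protein row indices, used by the heuristic prefilter
build_seed_index <- function(db, k) {
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(db$proteins))) {
    for (km in peptide_kmers(db$proteins$aa_sequence[i], k)) {
      idx[[km]] <- c(idx[[km]], i)
    }
  }
  idx
}

#' Search one read against a tagged protein database
#'
#' Translates the read in six frames (segments split at stop codons),
#' aligns against the database subjects, and returns the best hit whose
#' e-value is strictly below the configured threshold, or `NULL` if none
#' passes. In exact mode every frame is aligned against every subject; in
#' heuristic mode only subjects sharing at least one seed k-peptide with
#' some frame are aligned, so heuristic hits are always a subset of exact
#' hits with identical scores and e-values. Ties are broken by larger raw
#' score, then lexicographically smaller subject id, then frame order
#' (+1, +2, +3, -1, -2, -3).
#'
#' The e-value of a hit uses the frame peptide length as `m` and the total
#' residue count of the searched database as `n` (also in heuristic mode,
#' so the two modes agree hit-for-hit).
#'
#' @param read One-row data frame (or list) with `read_id` and
#'   `nt_sequence`, as produced by [read_sequences()].
#' @param db A non-empty [cog_database()].
#' @param config A [search_config()] (`engine_mode` `"exact"` or
#'   `"heuristic"`).
#' @param scheme A [scoring_scheme()].
#' @param seed_index Optional prebuilt index from repeated heuristic
#'   searches; built on the fly when absent.
#' @return A list (`query_id`, `subject_id`, `frame`, `raw_score`,
#'   `bit_score`, `evalue`, `q_aa_start`, `q_aa_end`, `s_start`, `s_end`,
#'   `identity_fraction`) or `NULL`.
#' @export
search_read <- function(read, db, config = search_config(),
                        scheme = scoring_scheme(), seed_index = NULL) {
  stopifnot(inherits(db, "cog_database"))
  if (nrow(db$proteins) == 0L) stop("database is empty")
  nt <- if (is.data.frame(read)) read$nt_sequence[1L] else read$nt_sequence
  qid <- if (is.data.frame(read)) read$read_id[1L] else read$read_id
  if (nchar(nt) < 3L) {
    warning("read ", qid, " shorter than one codon; returning no hit")
    return(NULL)
  }
  frames <- six_frame_translate(nt, scheme$genetic_code)
  frame_names <- names(frames)
  segs <- list()
  for (f in frame_names) {
    sp <- split_at_stops(frames[[f]])
    if (nrow(sp) == 0L) next
    sp$frame <- f
    sp$m <- nchar(frames[[f]])
    segs[[length(segs) + 1L]] <- sp
  }
  if (length(segs) == 0L) return(NULL)
  segs <- do.call(rbind, segs)

  n_db <- db_total_residues(db)
  if (config$engine_mode == "heuristic") {
    if (is.null(seed_index)) {
      seed_index <- build_seed_index(db, config$seed_word_length)
    }
    cand <- integer()
    for (s in segs$segment) {
      for (km in peptide_kmers(s, config$seed_word_length)) {
        hit <- seed_index[[km]]
        if (!is.null(hit)) cand <- c(cand, hit)
      }
    }
    cand <- sort(unique(cand))
    if (length(cand) == 0L) return(NULL)
  } else {
    cand <- seq_len(nrow(db$proteins))
  }
  subjects <- db$proteins$aa_sequence[cand]
  scores <- sw_scores(segs$segment, subjects, scheme)

  # best hit: smallest e-value, then larger raw score, then subject id, frame
  best <- NULL
  lam <- scheme$lambda
  for (j in seq_along(cand)) {
    for (i in seq_len(nrow(segs))) {
      sc <- scores[i, j]
      if (sc <= 0L) next
      ev <- scheme$kappa * segs$m[i] * n_db * exp(-lam * sc)
      if (ev >= config$evalue_threshold) next
      sid <- db$proteins$protein_id[cand[j]]
      fr <- match(segs$frame[i], frame_names)
      if (is.null(best) || ev < best$ev ||
          (ev == best$ev && (sc > best$sc ||
             (sc == best$sc && (sid < best$sid ||
                (sid == best$sid && fr < best$fr)))))) {
        best <- list(ev = ev, sc = sc, sid = sid, fr = fr,
                     seg_row = i, cand_col = j, m = segs$m[i])
      }
    }
  }
  if (is.null(best)) return(NULL)

  al <- local_align(segs$segment[best$seg_row],
                    db$proteins$aa_sequence[cand[best$cand_col]], scheme)
  be <- score_to_evalue(best$sc, best$m, n_db, scheme)
  list(query_id = qid,
       subject_id = best$sid,
       frame = frame_names[best$fr],
       raw_score = best$sc,
       bit_score = be$bit_score,
       evalue = be$evalue,
       q_aa_start = al$q_aa_start + segs$offset[best$seg_row],
       q_aa_end = al$q_aa_end + segs$offset[best$seg_row],
       s_start = al$s_start,
       s_end = al$s_end,
       identity_fraction = al$identity_fraction)
}
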
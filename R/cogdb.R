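#' The 25 single-letter COG functional category codes
#'
#' Order follows the conventional COG listing (information storage and
#' processing, cellular processes, metabolism, poorly characterized).
#'
#' @return Character vector of 25 distinct single-letter codes.
#' @export
category_alphabet <- function() {
  c("J", "A", "K", "L", "B", "D", "Y", "V", "T", "M", "N", "Z", "W",
    "U", "O", "C", "G", "E", "F", "H", "I", "P", "Q", "R", "S")
}

#' Construct a tagged COG protein database
#'
#' A database is a data frame of protein records plus a `kind` flag and, for
#' reduced (representative) databases, a provenance table recording which
#' member proteins each representative stands for. Category tags are stored
#' as concatenated single-letter codes (e.g. `"CE"` for a protein in both
#' energy production and amino-acid metabolism).
#'
#' @param proteins Data frame with columns `protein_id` (unique, non-empty),
#'   `aa_sequence` (non-empty, 20 amino acids plus `X`), `cog_id`,
#'   `categories` (non-empty string of category letters).
#' @param kind `"full"` or `"reduced"`.
#' @param provenance For reduced databases, a data frame with columns
#'   `category`, `representative_id`, `member_id`.
#' @return An object of class `"cog_database"`.
#' @export
cog_database <- function(proteins, kind = c("full", "reduced"), provenance = NULL) {
  kind <- match.arg(kind)
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  req <- c("protein_id", "aa_sequence", "cog_id", "categories")
  if (!all(req %in% names(proteins))) {
    stop("proteins must have columns: ", paste(req, collapse = ", "))
  }
  proteins <- proteins[, req]
  if (anyDuplicated(proteins$protein_id)) {
    dups <- unique(proteins$protein_id[duplicated(proteins$protein_id)])
    stop("duplicate protein_id: ", paste(dups, collapse = ", "))
  }
  if (any(!nzchar(proteins$protein_id))) stop("protein_id must be non-empty")
  if (any(!nzchar(proteins$aa_sequence))) stop("aa_sequence must be non-empty")
  ok_aa <- grepl(paste0("^[", paste(c(aa_alphabet(), "X"), collapse = ""), "]+$"),
                 proteins$aa_sequence)
  if (any(!ok_aa)) {
    stop("invalid amino-acid sequence for: ",
         paste(utils::head(proteins$protein_id[!ok_aa]), collapse = ", "))
  }
  cat_ok <- vapply(strsplit(proteins$categories, ""), function(cc) {
    length(cc) > 0L && all(cc %in% category_alphabet()) && !anyDuplicated(cc)
  }, logical(1))
  if (any(!cat_ok)) {
    stop("invalid category tags for: ",
         paste(utils::head(proteins$protein_id[!cat_ok]), collapse = ", "))
  }
  if (kind == "reduced") {
    if (is.null(provenance)) stop("reduced databases require provenance")
    provenance <- as.data.frame(provenance, stringsAsFactors = FALSE)
    preq <- c("category", "representative_id", "member_id")
    if (!all(preq %in% names(provenance))) {
      stop("provenance must have columns: ", paste(preq, collapse = ", "))
    }
    provenance <- provenance[, preq]
    if (!all(provenance$representative_id %in% proteins$protein_id)) {
      stop("provenance representatives missing from proteins")
    }
  }
  rownames(proteins) <- NULL
  structure(list(proteins = proteins, kind = kind, provenance = provenance),
            class = "cog_database")
}

#' @export
print.cog_database <- function(x, ...) {
  cats <- sort(unique(unlist(strsplit(x$proteins$categories, ""))))
  cat("COG database (", x$kind, "): ", nrow(x$proteins), " proteins, ",
      length(unique(x$proteins$cog_id)), " COGs, ", length(cats),
      " categories\n", sep = "")
  invisible(x)
}

db_total_residues <- function(db) sum(nchar(db$proteins$aa_sequence))

categories_present <- function(db) {
  sort(unique(unlist(strsplit(db$proteins$categories, ""))))
}

#' Partition a database by functional category
#'
#' A protein tagged with k categories appears in k partitions; the union of
#' all partitions is the full protein set. This is the database side of the
#' directed-search strategy: stage 2 searches only the partition(s) matching
#' a read's tentative category.
#'
#' @param db A [cog_database()].
#' @return Named list mapping each category code present in `db` to the data
#'   frame of proteins carrying that tag.
#' @export
partition_by_category <- function(db) {
  stopifnot(inherits(db, "cog_database"))
  cats <- categories_present(db)
  out <- lapply(cats, function(cc) {
    db$proteins[grepl(cc, db$proteins$categories, fixed = TRUE), , drop = FALSE]
  })
  names(out) <- cats
  out
}

#' Greedy identity clustering of one category's proteins
#'
#' Proteins are visited in order of decreasing sequence length (ties broken
#' by lexicographic id). Each protein joins the first existing cluster whose
#' representative it matches at or above `identity_threshold`, else founds a
#' new cluster. Identity is CD-HIT style: identical aligned residues in the
#' best local alignment divided by the length of the shorter sequence, so a
#' short spurious match cannot merge unrelated proteins. After assignment
#' each cluster's representative is its longest member (ties: smallest id).
#'
#' @param proteins Data frame of protein records sharing the category being
#'   clustered (columns as in [cog_database()]).
#' @param identity_threshold Identity fraction in (0, 1); default 0.6.
#' @param scheme A [scoring_scheme()].
#' @return List of clusters, each `list(member_ids, representative_id)`.
#' @export
cluster_category <- function(proteins, identity_threshold = 0.6,
                             scheme = scoring_scheme()) {
  if (!(identity_threshold > 0 && identity_threshold < 1)) {
    stop("identity_threshold must be in (0, 1)")
  }
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  if (nrow(proteins) == 0L) return(list())
  ord <- order(-nchar(proteins$aa_sequence), proteins$protein_id)
  proteins <- proteins[ord, , drop = FALSE]
  clusters <- list()  # each: list(member_ids, member_seqs, rep_seq)
  for (i in seq_len(nrow(proteins))) {
    id <- proteins$protein_id[i]
    seq_i <- proteins$aa_sequence[i]
    placed <- FALSE
    for (k in seq_along(clusters)) {
      rep_seq <- clusters[[k]]$rep_seq
      al <- local_align(seq_i, rep_seq, scheme)
      ident <- al$matches / min(nchar(seq_i), nchar(rep_seq))
      if (ident >= identity_threshold) {
        clusters[[k]]$member_ids <- c(clusters[[k]]$member_ids, id)
        clusters[[k]]$member_seqs <- c(clusters[[k]]$member_seqs, seq_i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <-
        list(member_ids = id, member_seqs = seq_i, rep_seq = seq_i)
    }
  }
  lapply(clusters, function(cl) {
    lens <- nchar(cl$member_seqs)
    best <- order(-lens, cl$member_ids)[1L]
    list(member_ids = sort(cl$member_ids), representative_id = cl$member_ids[best])
  })
}

#' Build the reduced (representative) database
#'
#' Clusters each functional category independently with [cluster_category()]
#' and pools the longest member of every cluster, tagged with the category it
#' was clustered under, into a new database of kind `"reduced"`. A protein
#' selected as representative under several categories yields one record
#' carrying the union of those tags. Cluster membership is recorded in the
#' provenance table. The reduced database is never larger than the full one
#' and conserves its category codes.
#'
#' @param full A [cog_database()] of kind `"full"`.
#' @param identity_threshold Clustering identity threshold, default 0.6.
#' @param scheme A [scoring_scheme()].
#' @return A [cog_database()] of kind `"reduced"`.
#' @export
build_reduced_db <- function(full, identity_threshold = 0.6,
                             scheme = scoring_scheme()) {
  stopifnot(inherits(full, "cog_database"))
  if (full$kind != "full") stop("build_reduced_db expects a full database")
  parts <- partition_by_category(full)
  rep_rows <- list()
  prov <- list()
  for (cc in names(parts)) {
    cls <- cluster_category(parts[[cc]], identity_threshold, scheme)
    for (cl in cls) {
      rid <- cl$representative_id
      src <- full$proteins[full$proteins$protein_id == rid, ]
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        protein_id = rid, aa_sequence = src$aa_sequence,
        cog_id = src$cog_id, categories = cc, stringsAsFactors = FALSE)
      prov[[length(prov) + 1L]] <- data.frame(
        category = cc, representative_id = rid, member_id = cl$member_ids,
        stringsAsFactors = FALSE)
    }
  }
  reps <- do.call(rbind, rep_rows)
  # merge a representative chosen under several categories into one record
  merged <- lapply(split(reps, reps$protein_id), function(d) {
    cats <- unique(unlist(strsplit(d$categories, "")))
    cats <- cats[order(match(cats, category_alphabet()))]
    d <- d[1L, , drop = FALSE]
    d$categories <- paste(cats, collapse = "")
    d
  })
  merged <- do.call(rbind, merged)
  merged <- merged[order(merged$protein_id), , drop = FALSE]
  cog_database(merged, kind = "reduced", provenance = do.call(rbind, prov))
}

#' Read a tagged protein database from FASTA
#'
#' Headers must follow the dialect `>protein_id|cog_id|CATEGORIES`, e.g.
#' `>P0001|COG0443|O`; categories are concatenated single letters. Headers
#' missing either field are rejected.
#'
#' @param path FASTA file path.
#' @param kind Database kind to stamp on the result.
#' @param provenance Optional provenance table for reduced databases.
#' @return A [cog_database()].
#' @export
read_tagged_fasta <- function(path, kind = "full", provenance = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  aas <- Biostrings::readAAStringSet(path)
  hdr <- names(aas)
  fields <- strsplit(sub("\\s.*$", "", hdr), "|", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    stop("malformed tagged-FASTA header (need id|cog|categories): ",
         hdr[which(nf != 3L)[1L]])
  }
  proteins <- data.frame(
    protein_id = vapply(fields, `[`, "", 1L),
    aa_sequence = toupper(as.character(aas)),
    cog_id = vapply(fields, `[`, "", 2L),
    categories = vapply(fields, `[`, "", 3L),
    stringsAsFactors = FALSE)
  if (any(!nzchar(proteins$cog_id)) || any(!nzchar(proteins$categories))) {
    stop("tagged-FASTA header with empty cog or category field")
  }
  cog_database(proteins, kind = kind, provenance = provenance)
}

#' Write a tagged protein database to FASTA (plus optional provenance TSV)
#'
#' @param db A [cog_database()].
#' @param path Output FASTA path.
#' @param provenance_path Optional path for the provenance TSV
#'   (`category`, `representative_id`, `member_id`) of a reduced database.
#' @return Invisibly, `path`.
#' @export
write_tagged_fasta <- function(db, path, provenance_path = NULL) {
  stopifnot(inherits(db, "cog_database"))
  seqs <- Biostrings::AAStringSet(db$proteins$aa_sequence)
  names(seqs) <- paste(db$proteins$protein_id, db$proteins$cog_id,
                       db$proteins$categories, sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  if (!is.null(provenance_path)) {
    if (is.null(db$provenance)) stop("database has no provenance to write")
    utils::write.table(db$provenance, provenance_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
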
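#' Build the COG cross-mapping store
#'
#' Collates per-COG term sets in the KEGG, Pfam, GO and SEED namespaces from
#' two source classes: `curated_import` (mined mapping tables) and
#' `homology` (sequence-search-derived rows). For each (COG, namespace)
#' pair, if both sources contribute and their term sets differ, the
#' homology-derived set is kept wholesale and the disagreement is logged;
#' if the sets agree or only one source contributes, the union is kept.
#' GO terms are additionally derived by relational composition
#' COG -> Pfam -> GO through the `pfam2go` pairs and merged with any direct
#' GO rows. The result is deterministic and independent of row order. GO
#' terms are not propagated up the ontology.
#'
#' @param rows Data frame with columns `cog_id`, `namespace` (one of
#'   `KEGG`, `PFAM`, `GO`, `SEED`), `term_id`, `source` (`curated_import`
#'   or `homology`).
#' @param pfam2go Optional data frame with columns `pfam_id`, `go_id`
#'   (e.g. from [parse_pfam2go()]).
#' @return An object of class `"cog_crossmap"`: list with `entries`
#'   (data frame `cog_id`, `namespace`, `term_id`, sorted) and
#'   `conflict_log` (data frame `cog_id`, `namespace`, `discarded`, `kept`,
#'   term sets `;`-joined).
#' @examples
#' rows <- data.frame(cog_id = "COG0001", namespace = "KEGG",
#'                    term_id = c("K00001", "K00002"),
#'                    source = c("curated_import", "homology"))
#' xm <- build_crossmap(rows)
#' xm$entries$term_id      # "K00002" -- homology wins on conflict
#' @export
build_crossmap <- function(rows, pfam2go = NULL) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  req <- c("cog_id", "namespace", "term_id", "source")
  if (nrow(rows) > 0L && !all(req %in% names(rows))) {
    stop("rows must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(rows) == 0L) {
    rows <- data.frame(cog_id = character(), namespace = character(),
                       term_id = character(), source = character())
  }
  ok_ns <- rows$namespace %in% c("KEGG", "PFAM", "GO", "SEED")
  if (any(!ok_ns)) {
    stop("unknown namespace: ", paste(unique(rows$namespace[!ok_ns]), collapse = ", "))
  }
  ok_src <- rows$source %in% c("curated_import", "homology")
  if (any(!ok_src)) {
    stop("unknown source: ", paste(unique(rows$source[!ok_src]), collapse = ", "))
  }
  if (any(!nzchar(rows$term_id)) || any(!nzchar(rows$cog_id))) {
    stop("cog_id and term_id must be non-empty")
  }

  entries <- list()
  conflicts <- list()
  key <- paste(rows$cog_id, rows$namespace, sep = "\r")
  for (k in sort(unique(key))) {
    d <- rows[key == k, ]
    cur <- sort(unique(d$term_id[d$source == "curated_import"]))
    hom <- sort(unique(d$term_id[d$source == "homology"]))
    if (length(cur) > 0L && length(hom) > 0L && !setequal(cur, hom)) {
      kept <- hom
      conflicts[[length(conflicts) + 1L]] <- data.frame(
        cog_id = d$cog_id[1L], namespace = d$namespace[1L],
        discarded = paste(cur, collapse = ";"),
        kept = paste(hom, collapse = ";"), stringsAsFactors = FALSE)
    } else {
      kept <- sort(union(cur, hom))
    }
    entries[[length(entries) + 1L]] <- data.frame(
      cog_id = d$cog_id[1L], namespace = d$namespace[1L], term_id = kept,
      stringsAsFactors = FALSE)
  }
  entries <- if (length(entries) > 0L) do.call(rbind, entries)
    else data.frame(cog_id = character(), namespace = character(),
                    term_id = character())

  # GO by composition through the kept Pfam sets
  if (!is.null(pfam2go) && nrow(pfam2go) > 0L) {
    pf <- entries[entries$namespace == "PFAM", , drop = FALSE]
    go <- merge(pf, as.data.frame(pfam2go, stringsAsFactors = FALSE),
                by.x = "term_id", by.y = "pfam_id")
    if (nrow(go) > 0L) {
      entries <- rbind(entries, data.frame(
        cog_id = go$cog_id, namespace = "GO", term_id = go$go_id,
        stringsAsFactors = FALSE))
    }
  }
  entries <- unique(entries)
  entries <- entries[order(entries$cog_id, entries$namespace, entries$term_id), ]
  rownames(entries) <- NULL
  conflict_log <- if (length(conflicts) > 0L) do.call(rbind, conflicts)
    else data.frame(cog_id = character(), namespace = character(),
                    discarded = character(), kept = character())
  structure(list(entries = entries, conflict_log = conflict_log),
            class = "cog_crossmap")
}

#' @export
print.cog_crossmap <- function(x, ...) {
  cat("Cross-mapping store: ", length(unique(x$entries$cog_id)), " COGs, ",
      nrow(x$entries), " term rows, ", nrow(x$conflict_log),
      " logged conflicts\n", sep = "")
  invisible(x)
}

#' Parse a pfam2go-format flat file
#'
#' Reads the GO-site external2go dialect, e.g.
#' `Pfam:PF00001 7tm_1 > GO:G protein-coupled receptor activity ; GO:0004930`.
#' Lines starting with `!` are comments.
#'
#' @param path Flat file path.
#' @return Data frame with columns `pfam_id`, `go_id`.
#' @export
parse_pfam2go <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(trimws(lines))]
  pf <- regmatches(lines, regexpr("^Pfam:(PF[0-9]+)", lines))
  go <- regmatches(lines, regexpr("GO:[0-9]+\\s*$", lines))
  if (length(pf) != length(lines) || length(go) != length(lines)) {
    stop("malformed pfam2go line in ", path)
  }
  data.frame(pfam_id = sub("^Pfam:", "", pf), go_id = trimws(go),
             stringsAsFactors = FALSE)
}

crossmap_terms <- function(xmap, cog_id, namespace) {
  e <- xmap$entries
  e$term_id[e$cog_id == cog_id & e$namespace == namespace]
}

#' Derive all annotation namespaces from COG assignments
#'
#' The "mapping" phase: each read's COG call is expanded into KEGG, Pfam,
#' GO and SEED term sets by pure lookup in the cross-mapping store - no
#' alignment work happens here. Unassigned reads yield all-empty records; a
#' COG absent from the store keeps its COG and category labels with the four
#' derived namespaces empty.
#'
#' @param assignments Data frame of COG assignments as returned in the
#'   `assignments` element of [annotate_reads()] (columns `read_id`,
#'   `cog_id`, `category`; `NA` for unassigned reads).
#' @param xmap A [build_crossmap()] store.
#' @return Annotation data frame (`read_id`, `cog`, `category`, `kegg`,
#'   `pfam`, `go`, `seed`; `;`-joined multi-values, `""` for none).
#' @export
transfer_annotations <- function(assignments, xmap) {
  stopifnot(inherits(xmap, "cog_crossmap"))
  e <- xmap$entries
  idx <- split(e$term_id, paste(e$cog_id, e$namespace, sep = "\r"))
  lk <- function(cog, ns) {
    v <- idx[[paste(cog, ns, sep = "\r")]]
    if (is.null(v)) "" else paste(v, collapse = ";")
  }
  out <- empty_annotation_records(assignments$read_id)
  for (i in seq_len(nrow(assignments))) {
    cog <- assignments$cog_id[i]
    if (is.na(cog)) next
    out$cog[i] <- cog
    out$category[i] <- paste(strsplit(assignments$category[i], "")[[1]],
                             collapse = ";")
    out$kegg[i] <- lk(cog, "KEGG")
    out$pfam[i] <- lk(cog, "PFAM")
    out$go[i] <- lk(cog, "GO")
    out$seed[i] <- lk(cog, "SEED")
  }
  out
}

#' Serialize a cross-mapping store to TSV
#'
#' @param xmap A [build_crossmap()] store.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_crossmap <- function(xmap, path) {
  stopifnot(inherits(xmap, "cog_crossmap"))
  utils::write.table(xmap$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a serialized cross-mapping store
#'
#' Rebuilding a store from its own serialized form reproduces it exactly
#' (conflicts were already resolved before serialization, so the conflict
#' log of a reloaded store is empty).
#'
#' @param path TSV path written by [write_crossmap()].
#' @return A `"cog_crossmap"` object.
#' @export
read_crossmap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  e <- utils::read.delim(path, colClasses = "character")
  if (!identical(names(e), c("cog_id", "namespace", "term_id"))) {
    stop("unexpected crossmap columns in ", path)
  }
  rows <- data.frame(cog_id = e$cog_id, namespace = e$namespace,
                     term_id = e$term_id, source = "curated_import",
                     stringsAsFactors = FALSE)
  build_crossmap(rows)
}
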
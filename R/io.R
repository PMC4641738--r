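#' Read nucleotide sequences from FASTA or FASTQ
#'
#' Sequences are uppercased on ingestion; record order is preserved. Read
#' ids are the first whitespace-delimited token of each header and must be
#' unique within a file. FASTQ qualities (Sanger scale) are kept but unused
#' downstream; a quality string whose length differs from its sequence is a
#' parse error reported with its line number.
#'
#' @param path Input file.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (detect from the file
#'   extension, falling back to the first character: `>` FASTA, `@` FASTQ).
#' @return Data frame with columns `read_id`, `nt_sequence`, `quality`
#'   (`NA` for FASTA input).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fa", "fasta", "fna", "ffn")) "fasta"
      else if (ext %in% c("fq", "fastq")) "fastq"
      else {
        first <- substr(readLines(path, n = 1L), 1L, 1L)
        if (identical(first, ">")) "fasta"
        else if (identical(first, "@")) "fastq"
        else stop("cannot detect format of ", path)
      }
  }
  if (format == "fasta") {
    seqs <- Biostrings::readBStringSet(path, format = "fasta")
    out <- data.frame(
      read_id = sub("\\s.*$", "", names(seqs)),
      nt_sequence = toupper(as.character(seqs)),
      quality = NA_character_, stringsAsFactors = FALSE)
  } else {
    validate_fastq_structure(path)
    seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                         with.qualities = TRUE)
    out <- data.frame(
      read_id = sub("\\s.*$", "", names(seqs)),
      nt_sequence = toupper(as.character(seqs)),
      quality = as.character(S4Vectors::mcols(seqs)$qualities),
      stringsAsFactors = FALSE)
  }
  if (any(!nzchar(out$read_id))) stop("empty read id in ", path)
  if (anyDuplicated(out$read_id)) {
    dups <- unique(out$read_id[duplicated(out$read_id)])
    stop("duplicate read id(s): ", paste(dups, collapse = ", "))
  }
  if (any(nchar(out$nt_sequence) == 0L)) {
    stop("empty sequence for read ",
         out$read_id[which(nchar(out$nt_sequence) == 0L)[1L]])
  }
  rownames(out) <- NULL
  out
}

# Check four-line FASTQ structure up front so malformed records are reported
# with a line number instead of surfacing as an opaque parser failure.
validate_fastq_structure <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record at line ",
         length(lines) - (length(lines) %% 4L) + 1L, " of ", path)
  }
  for (i in seq(1L, length(lines), by = 4L)) {
    if (!startsWith(lines[i], "@")) {
      stop("FASTQ parse error at line ", i, ": header must start with '@'")
    }
    if (!startsWith(lines[i + 2L], "+")) {
      stop("FASTQ parse error at line ", i + 2L, ": separator must start with '+'")
    }
    if (nchar(lines[i + 3L]) != nchar(lines[i + 1L])) {
      stop("FASTQ parse error at line ", i + 3L,
           ": quality length ", nchar(lines[i + 3L]),
           " != sequence length ", nchar(lines[i + 1L]))
    }
  }
  invisible(TRUE)
}

#' Parse a 12-column tabular hit file from an external aligner
#'
#' Accepts the de-facto tab-separated hit-table dialect (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, e-value, bit score). Comment lines starting
#' with `#` are skipped. Coordinates are 1-based inclusive.
#'
#' @param path Hit file path.
#' @return Data frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bit_score`, rows in
#'   file order.
#' @export
parse_external_hits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  line_no <- which(keep)
  bad <- which(lengths(rows) != 12L)
  if (length(bad) > 0L) {
    stop("hit row at line ", line_no[bad[1L]], " has ",
         lengths(rows)[bad[1L]], " columns; expected 12")
  }
  if (length(rows) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(), alignment_length = integer(),
                      mismatches = integer(), gap_opens = integer(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      evalue = numeric(), bit_score = numeric()))
  }
  m <- do.call(rbind, rows)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      stop("non-numeric ", what, " at line ", line_no[which(is.na(v))[1L]])
    }
    v
  }
  out <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    percent_identity = num(3L, "percent identity"),
    alignment_length = as.integer(num(4L, "alignment length")),
    mismatches = as.integer(num(5L, "mismatch count")),
    gap_opens = as.integer(num(6L, "gap open count")),
    q_start = as.integer(num(7L, "query start")),
    q_end = as.integer(num(8L, "query end")),
    s_start = as.integer(num(9L, "subject start")),
    s_end = as.integer(num(10L, "subject end")),
    evalue = num(11L, "evalue"), bit_score = num(12L, "bit score"),
    stringsAsFactors = FALSE)
  if (any(out$evalue < 0)) {
    stop("negative evalue at line ", line_no[which(out$evalue < 0)[1L]])
  }
  out
}

annotation_namespaces <- function() c("cog", "category", "kegg", "pfam", "go", "seed")

#' Canonical empty annotation record set
#'
#' One all-empty annotation row per read id, in the fixed namespace order
#' `cog`, `category`, `kegg`, `pfam`, `go`, `seed`.
#'
#' @param read_ids Character vector of read ids.
#' @return Annotation data frame with empty-string cells.
#' @export
empty_annotation_records <- function(read_ids = character()) {
  out <- data.frame(read_id = read_ids, stringsAsFactors = FALSE)
  for (ns in annotation_namespaces()) out[[ns]] <- rep("", length(read_ids))
  out
}

#' Write an annotation table to TSV
#'
#' One row per read in the fixed column order `read_id`, `cog`, `category`,
#' `kegg`, `pfam`, `go`, `seed`. Multi-valued cells are joined with `;`,
#' empty cells written as `-`; both conventions are stated in a `#` comment
#' at the top of the file. The table round-trips losslessly through
#' [read_annotation_table()].
#'
#' @param records Annotation data frame (columns above; empty string for
#'   no annotation, `;`-joined multi-values).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation_table <- function(records, path) {
  req <- c("read_id", annotation_namespaces())
  if (!all(req %in% names(records))) {
    stop("records must have columns: ", paste(req, collapse = ", "))
  }
  records <- records[, req]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# multi-valued cells joined by ';'; unannotated cells are '-'",
               paste(req, collapse = "\t")), con)
  body <- records
  for (ns in req[-1L]) body[[ns]][!nzchar(body[[ns]])] <- "-"
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an annotation table written by [write_annotation_table()]
#'
#' @param path Input TSV path.
#' @return Annotation data frame with `-` cells restored to empty strings.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  out <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           colClasses = "character", check.names = FALSE)
  req <- c("read_id", annotation_namespaces())
  if (!identical(names(out), req)) {
    stop("unexpected annotation table columns in ", path)
  }
  for (ns in req[-1L]) out[[ns]][out[[ns]] == "-"] <- ""
  out
}
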
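#' Six-frame translation of a nucleotide sequence
#'
#' Translates a read in all six reading frames: `+1`, `+2`, `+3` are the
#' given strand at offsets 0, 1, 2; `-1`, `-2`, `-3` are the reverse
#' complement at the same offsets. Stop codons are rendered `*`; any codon
#' containing `N` translates to `X`; trailing bases shorter than a full codon
#' are dropped.
#'
#' @param nt_sequence A single nucleotide string over `A,C,G,T,N`
#'   (lowercase accepted).
#' @param genetic_code Codon table, default the standard genetic code.
#' @return Named character vector of six peptides, names
#'   `"+1","+2","+3","-1","-2","-3"`; frames shorter than one codon are `""`.
#' @examples
#' six_frame_translate("ATGAAA")[["+1"]]  # "MK"
#' @export
six_frame_translate <- function(nt_sequence,
                                genetic_code = Biostrings::GENETIC_CODE) {
  if (!is.character(nt_sequence) || length(nt_sequence) != 1L || is.na(nt_sequence)) {
    stop("nt_sequence must be a single string")
  }
  nt <- toupper(nt_sequence)
  bad <- setdiff(unique(strsplit(nt, "", fixed = TRUE)[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    stop("invalid nucleotide symbol(s): ", paste(bad, collapse = ", "))
  }
  fwd <- nt
  rev <- chartr("ACGTN", "TGCAN", paste(base::rev(strsplit(nt, "")[[1]]),
                                        collapse = ""))
  frame_pep <- function(seq_str, offset) {
    len <- nchar(seq_str) - offset
    len <- len - (len %% 3L)
    if (len < 3L) return("")
    starts <- seq.int(offset + 1L, offset + len, by = 3L)
    codons <- substring(seq_str, starts, starts + 2L)
    aa <- unname(genetic_code[codons])
    aa[is.na(aa)] <- "X"  # any codon containing N
    paste(aa, collapse = "")
  }
  out <- c(
    "+1" = frame_pep(fwd, 0L), "+2" = frame_pep(fwd, 1L), "+3" = frame_pep(fwd, 2L),
    "-1" = frame_pep(rev, 0L), "-2" = frame_pep(rev, 1L), "-3" = frame_pep(rev, 2L)
  )
  out
}

# Split a peptide at stop codons into alignable segments.
# Returns data.frame(segment, offset) where offset is the 0-based position of
# the segment within the frame peptide; empty segments are dropped.
split_at_stops <- function(peptide) {
  if (nchar(peptide) == 0L) {
    return(data.frame(segment = character(), offset = integer()))
  }
  parts <- strsplit(peptide, "*", fixed = TRUE)[[1]]
  if (length(parts) == 0L) {
    return(data.frame(segment = character(), offset = integer()))
  }
  offs <- cumsum(c(0L, nchar(parts[-length(parts)]) + 1L))
  keep <- nchar(parts) > 0L
  data.frame(segment = parts[keep], offset = offs[keep])
}
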
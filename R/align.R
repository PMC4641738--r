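#' Local protein alignment under affine gaps
#'
#' Smith-Waterman alignment of two peptides under the scheme's substitution
#' matrix and affine gap penalties. Peptides may contain stop symbols `*`;
#' the sequences are split at stops and segments aligned independently, so a
#' local alignment never crosses a stop codon. When no positive-scoring
#' alignment exists the raw score is 0 and the coordinates are `NA`.
#'
#' Among co-optimal alignments the one with the smallest query start, then
#' smallest subject start, is returned, making results deterministic.
#'
#' @param query_peptide,subject_peptide Non-empty peptide strings.
#' @param scheme A [scoring_scheme()].
#' @return A list with `raw_score` (integer, >= 0), 1-based inclusive
#'   coordinates `q_aa_start`, `q_aa_end`, `s_start`, `s_end`, and
#'   `identity_fraction` (identical aligned residues / alignment columns).
#' @examples
#' local_align("MKW", "MKW", scoring_scheme())$raw_score  # 21
#' @export
local_align <- function(query_peptide, subject_peptide, scheme = scoring_scheme()) {
  stopifnot(is.character(query_peptide), length(query_peptide) == 1L,
            is.character(subject_peptide), length(subject_peptide) == 1L)
  if (nchar(query_peptide) == 0L || nchar(subject_peptide) == 0L) {
    stop("peptides must be non-empty")
  }
  qsegs <- split_at_stops(query_peptide)
  ssegs <- split_at_stops(subject_peptide)
  best <- list(raw_score = 0L, q_aa_start = NA_integer_, q_aa_end = NA_integer_,
               s_start = NA_integer_, s_end = NA_integer_,
               identity_fraction = 0, matches = 0L, aln_length = 0L)
  if (nrow(qsegs) == 0L || nrow(ssegs) == 0L) return(best)
  for (i in seq_len(nrow(qsegs))) {
    for (j in seq_len(nrow(ssegs))) {
      al <- sw_traceback(qsegs$segment[i], ssegs$segment[j], scheme)
      if (al$score <= 0L) next
      cand <- list(
        raw_score = al$score,
        q_aa_start = al$q_start + qsegs$offset[i],
        q_aa_end = al$q_end + qsegs$offset[i],
        s_start = al$s_start + ssegs$offset[j],
        s_end = al$s_end + ssegs$offset[j],
        identity_fraction = al$matches / al$aln_length,
        matches = al$matches, aln_length = al$aln_length
      )
      replace <- cand$raw_score > best$raw_score ||
        (cand$raw_score == best$raw_score &&
           (cand$q_aa_start < best$q_aa_start ||
              (cand$q_aa_start == best$q_aa_start && cand$s_start < best$s_start)))
      if (replace) best <- cand
    }
  }
  best
}

#' Bit score and Karlin-Altschul e-value for a raw alignment score
#'
#' Converts a raw local-alignment score `S` into a bit score and an expect
#' value using `E = K * m * n * exp(-lambda * S)` and
#' `bits = (lambda * S - ln K) / ln 2`, where `m` is the query peptide length
#' and `n` the total residue count of the searched database. The e-value is
#' the expected number of chance alignments scoring at least `S` in a search
#' space of that size, so it grows linearly with the database and shrinks
#' exponentially with the score.
#'
#' @param raw_score Non-negative integer alignment score.
#' @param m Query peptide length (>= 1).
#' @param n Total residue count of the searched database (>= 1).
#' @param scheme A [scoring_scheme()] supplying `lambda` and `kappa`.
#' @return List with `bit_score` and `evalue`.
#' @examples
#' score_to_evalue(0, 100, 100, scoring_scheme())$evalue  # 410
#' @export
score_to_evalue <- function(raw_score, m, n, scheme = scoring_scheme()) {
  if (!(m >= 1) || !(n >= 1)) stop("m and n must be positive")
  if (raw_score < 0) stop("raw_score must be non-negative")
  evalue <- scheme$kappa * m * n * exp(-scheme$lambda * raw_score)
  bits <- (scheme$lambda * raw_score - log(scheme$kappa)) / log(2)
  list(bit_score = bits, evalue = evalue)
}
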
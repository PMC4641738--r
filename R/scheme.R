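#' Amino-acid scoring scheme for the translated search engine
#'
#' Bundles everything the alignment and e-value layers need: a protein
#' substitution matrix, affine gap penalties, the Karlin-Altschul parameters
#' lambda and K used to convert raw Smith-Waterman scores into bit scores and
#' e-values, and the genetic code used for six-frame translation.
#'
#' The default matrix is BLOSUM62 restricted to the 20 standard amino acids
#' plus the ambiguity residue `X`; every pair involving `X` scores at most 0,
#' so residues arising from ambiguous codons can never create a match. The
#' default gap penalties follow the BLAST existence/extension convention: a
#' gap of length *k* scores `gap_open + k * gap_extend` (so -12 for a
#' single-residue gap at the defaults). `lambda = 0.267` and `kappa = 0.041`
#' are the standard gapped BLOSUM62-11-1 values; they are fixed constants, not
#' fit from data, so e-values are comparable across searches made with the
#' same scheme but are approximate in absolute terms.
#'
#' @param gap_open Gap opening score, a negative integer (default -11).
#' @param gap_extend Per-residue gap extension score, negative (default -1).
#' @param lambda,kappa Karlin-Altschul parameters, both positive.
#' @param substitution_matrix Optional symmetric integer matrix with
#'   single-letter amino-acid dimnames covering at least the 20 standard
#'   residues and `X`. Defaults to BLOSUM62.
#' @param genetic_code Named character vector mapping codons to amino acids
#'   (default the standard code from [Biostrings::GENETIC_CODE]).
#'
#' @return An object of class `"cog_scoring_scheme"`.
#' @examples
#' sch <- scoring_scheme()
#' sch$substitution_matrix["W", "W"]  # 11
#' @export
scoring_scheme <- function(gap_open = -11L, gap_extend = -1L,
                           lambda = 0.267, kappa = 0.041,
                           substitution_matrix = NULL,
                           genetic_code = Biostrings::GENETIC_CODE) {
  if (is.null(substitution_matrix)) {
    substitution_matrix <- default_blosum62()
  }
  gap_open <- as.integer(gap_open)
  gap_extend <- as.integer(gap_extend)
  if (gap_open >= 0L || gap_extend >= 0L) {
    stop("gap penalties must be negative integers")
  }
  if (!(lambda > 0) || !(kappa > 0)) {
    stop("lambda and kappa must be positive")
  }
  m <- substitution_matrix
  if (!is.matrix(m) || is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    stop("substitution_matrix must be a square matrix with matching dimnames")
  }
  if (!isTRUE(all.equal(m, t(m)))) stop("substitution_matrix must be symmetric")
  needed <- c(aa_alphabet(), "X")
  if (!all(needed %in% rownames(m))) {
    stop("substitution_matrix must cover the 20 amino acids plus X")
  }
  m <- m[needed, needed, drop = FALSE]
  storage.mode(m) <- "integer"
  if (any(m["X", ] > 0L)) stop("pairs involving X must score <= 0")
  if (!is.character(genetic_code) || is.null(names(genetic_code))) {
    stop("genetic_code must be a named codon -> amino-acid vector")
  }
  structure(
    list(substitution_matrix = m, gap_open = gap_open, gap_extend = gap_extend,
         lambda = lambda, kappa = kappa, genetic_code = genetic_code),
    class = "cog_scoring_scheme"
  )
}

#' @export
print.cog_scoring_scheme <- function(x, ...) {
  cat("Scoring scheme: ", nrow(x$substitution_matrix), "x",
      ncol(x$substitution_matrix), " substitution matrix, gaps ",
      x$gap_open, "/", x$gap_extend, ", lambda=", x$lambda,
      ", K=", x$kappa, "\n", sep = "")
  invisible(x)
}

# the 20 standard amino acids, in BLOSUM row order
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

default_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# shared engine-call counter: lets tests and the mapping phase demonstrate
# that annotation transfer performs zero alignment work
.engine_state <- new.env(parent = emptyenv())
.engine_state$calls <- 0L

#' Number of alignment-kernel invocations made so far
#'
#' A monotone counter incremented every time the package's Smith-Waterman
#' kernel is entered. Used to verify that the cross-mapping ("mapping") phase
#' is pure table lookup and triggers no alignment work.
#'
#' @return Integer count.
#' @export
alignment_call_count <- function() .engine_state$calls

sw_scores <- function(queries, subjects, scheme) {
  .engine_state$calls <- .engine_state$calls + 1L
  .sw_score_matrix_c(queries, subjects, scheme$substitution_matrix,
                     scheme$gap_open, scheme$gap_extend)
}

sw_traceback <- function(query, subject, scheme) {
  .engine_state$calls <- .engine_state$calls + 1L
  .sw_traceback_c(query, subject, scheme$substitution_matrix,
                  scheme$gap_open, scheme$gap_extend)
}
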
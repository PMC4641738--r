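# Independent full-matrix dynamic-programming oracle for local alignment.
# Coded from the Gotoh recurrences directly (whole H/E/F matrices, R loops),
# sharing no code with the package's C++ kernel. Gap of length k scores
# gap_open + k * gap_extend.

oracle_local_align <- function(q, s, scheme) {
  qv <- strsplit(q, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  M <- scheme$substitution_matrix
  go <- scheme$gap_open
  ge <- scheme$gap_extend
  m <- length(qv)
  n <- length(sv)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  for (i in seq_len(m) + 1L) {
    for (j in seq_len(n) + 1L) {
      E[i, j] <- max(H[i, j - 1] + go + ge, E[i, j - 1] + ge)
      F[i, j] <- max(H[i - 1, j] + go + ge, F[i - 1, j] + ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + M[qv[i - 1], sv[j - 1]],
                     E[i, j], F[i, j])
    }
  }
  best <- max(H)
  if (best <= 0) {
    return(list(score = 0L, matches = 0L, aln_length = 0L))
  }
  # traceback from the first maximal cell (row-major), diagonal preferred
  idx <- which(H == best, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  i <- idx[1, 1]; j <- idx[1, 2]
  matches <- 0L; len <- 0L; state <- "H"
  while (i > 1 && j > 1) {
    if (state == "H") {
      if (H[i, j] == 0) break
      if (H[i, j] == H[i - 1, j - 1] + M[qv[i - 1], sv[j - 1]]) {
        if (qv[i - 1] == sv[j - 1] && qv[i - 1] != "X") matches <- matches + 1L
        i <- i - 1L; j <- j - 1L; len <- len + 1L
      } else if (H[i, j] == F[i, j]) {
        state <- "F"
      } else {
        state <- "E"
      }
    } else if (state == "F") {
      len <- len + 1L
      if (F[i, j] == H[i - 1, j] + go + ge) state <- "H"
      i <- i - 1L
    } else {
      len <- len + 1L
      if (E[i, j] == H[i, j - 1] + go + ge) state <- "H"
      j <- j - 1L
    }
  }
  list(score = as.integer(best), matches = matches, aln_length = len)
}

# Exhaustive translated search oracle: all six frames (own translation from
# the standard codon table), all stop-free segments, all subjects; returns
# list(subject_id, score, evalue) for the best sub-threshold hit or NULL.
oracle_best_hit <- function(nt, db, scheme, threshold = 1e-5) {
  code <- Biostrings::GENETIC_CODE
  revcomp <- function(x) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  translate1 <- function(x) {
    n <- nchar(x) - nchar(x) %% 3
    if (n < 3) return("")
    starts <- seq(1, n, 3)
    aa <- vapply(substring(x, starts, starts + 2), function(cod) {
      if (grepl("N", cod)) "X" else code[[cod]]
    }, "")
    paste(aa, collapse = "")
  }
  peps <- character(6)
  for (k in 0:2) {
    peps[k + 1] <- translate1(substring(nt, k + 1))
    peps[k + 4] <- translate1(substring(revcomp(nt), k + 1))
  }
  n_db <- sum(nchar(db$proteins$aa_sequence))
  best <- NULL
  for (f in seq_len(6)) {
    m <- nchar(peps[f])
    segs <- strsplit(peps[f], "*", fixed = TRUE)[[1]]
    segs <- segs[nzchar(segs)]
    for (seg in segs) {
      for (r in seq_len(nrow(db$proteins))) {
        sc <- oracle_local_align(seg, db$proteins$aa_sequence[r], scheme)$score
        if (sc <= 0) next
        ev <- scheme$kappa * m * n_db * exp(-scheme$lambda * sc)
        if (ev >= threshold) next
        sid <- db$proteins$protein_id[r]
        if (is.null(best) || ev < best$evalue ||
            (ev == best$evalue && (sc > best$score ||
               (sc == best$score && sid < best$subject_id)))) {
          best <- list(subject_id = sid, score = sc, evalue = ev)
        }
      }
    }
  }
  best
}

random_peptide <- function(len) {
  paste(sample(metacog::scoring_scheme()$substitution_matrix |> rownames() |>
                 setdiff("X"), len, replace = TRUE), collapse = "")
}

mutate_peptide <- function(pep, rate) {
  aa <- setdiff(rownames(metacog::scoring_scheme()$substitution_matrix), "X")
  v <- strsplit(pep, "")[[1]]
  hit <- runif(length(v)) < rate
  v[hit] <- vapply(v[hit], function(old) sample(setdiff(aa, old), 1), "")
  paste(v, collapse = "")
}
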
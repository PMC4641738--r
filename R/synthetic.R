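#' Configuration for the synthetic fixture generator
#'
#' The generator emulates, in miniature, the structure the annotation
#' pipeline expects of its reference data: a tagged protein database with
#' several orthologous groups per functional category and several mutually
#' similar member proteins per group, a bijective cross-mapping truth table,
#' and nucleotide reads sampled from the proteins with known provenance.
#'
#' Defaults: all 25 categories, 2 COGs per category, 3 proteins per COG
#' derived from a common ancestor at 10% per-site substitution (so members
#' of one COG are ~80% pairwise identical while different COGs are
#' unrelated), 120-residue proteins, 150 nt error-free reads drawn from a
#' random strand.
#'
#' @param n_categories Number of category codes used (<= 25).
#' @param cogs_per_category COGs per category.
#' @param proteins_per_cog Member proteins per COG.
#' @param protein_length Protein length in residues.
#' @param intra_cog_substitution_rate Per-site substitution rate between a
#'   COG's ancestor and each member, in \[0, 1\].
#' @param n_reads Number of reads for [sample_reads()].
#' @param read_length_nt Read length in nucleotides.
#' @param nt_error_rate Per-base substitution error rate of reads.
#' @param revcomp_probability Probability a read is reverse-complemented.
#' @param seed Integer RNG seed; all generator outputs are pure functions
#'   of this configuration.
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_categories = 25L, cogs_per_category = 2L,
                              proteins_per_cog = 3L, protein_length = 120L,
                              intra_cog_substitution_rate = 0.1,
                              n_reads = 100L, read_length_nt = 150L,
                              nt_error_rate = 0, revcomp_probability = 0.5,
                              seed = 7L) {
  cfg <- list(n_categories = as.integer(n_categories),
              cogs_per_category = as.integer(cogs_per_category),
              proteins_per_cog = as.integer(proteins_per_cog),
              protein_length = as.integer(protein_length),
              intra_cog_substitution_rate = intra_cog_substitution_rate,
              n_reads = as.integer(n_reads),
              read_length_nt = as.integer(read_length_nt),
              nt_error_rate = nt_error_rate,
              revcomp_probability = revcomp_probability,
              seed = as.integer(seed))
  if (cfg$n_categories < 1L || cfg$n_categories > length(category_alphabet())) {
    stop("n_categories must be between 1 and ", length(category_alphabet()))
  }
  rates <- c(cfg$intra_cog_substitution_rate, cfg$nt_error_rate,
             cfg$revcomp_probability)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  lens <- c(cfg$cogs_per_category, cfg$proteins_per_cog, cfg$protein_length,
            cfg$n_reads, cfg$read_length_nt)
  if (any(lens < 1L)) stop("counts and lengths must be positive")
  structure(cfg, class = "simulation_config")
}

#' Generate a miniature tagged COG database and its truth cross-mapping
#'
#' For each of the first `n_categories` category codes, draws
#' `cogs_per_category` ancestor proteins i.i.d. uniform over the 20 amino
#' acids; each COG's member proteins are derived from the ancestor by
#' per-site substitution at `intra_cog_substitution_rate`. Every protein is
#' tagged with its category. The truth cross-mapping assigns each COG one
#' synthetic term per namespace (KEGG-, Pfam-, GO- and SEED-style ids),
#' bijectively, so derived-annotation accuracy against truth equals COG
#' accuracy. Deterministic under the configuration's seed.
#'
#' @param cfg A [simulation_config()].
#' @return List with `db` (a full [cog_database()]) and `xmap` (a
#'   `"cog_crossmap"` truth store).
#' @export
generate_toy_cogdb <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  aa <- aa_alphabet()
  cats <- category_alphabet()[seq_len(cfg$n_categories)]
  rows <- list()
  map_rows <- list()
  cog_no <- 0L
  for (cc in cats) {
    for (g in seq_len(cfg$cogs_per_category)) {
      cog_no <- cog_no + 1L
      cog_id <- sprintf("COG%04d", cog_no)
      ancestor <- sample(aa, cfg$protein_length, replace = TRUE)
      for (p in seq_len(cfg$proteins_per_cog)) {
        member <- ancestor
        mut <- stats::runif(cfg$protein_length) < cfg$intra_cog_substitution_rate
        if (any(mut)) {
          member[mut] <- vapply(member[mut], function(old) {
            sample(setdiff(aa, old), 1L)
          }, "")
        }
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = sprintf("%s_%d", cog_id, p),
          aa_sequence = paste(member, collapse = ""),
          cog_id = cog_id, categories = cc, stringsAsFactors = FALSE)
      }
      map_rows[[length(map_rows) + 1L]] <- data.frame(
        cog_id = cog_id,
        namespace = c("KEGG", "PFAM", "GO", "SEED"),
        term_id = c(sprintf("K%05d", cog_no), sprintf("PF%05d", cog_no),
                    sprintf("GO:%07d", cog_no), sprintf("SS%04d", cog_no)),
        source = "curated_import", stringsAsFactors = FALSE)
    }
  }
  db <- cog_database(do.call(rbind, rows), kind = "full")
  xmap <- build_crossmap(do.call(rbind, map_rows))
  list(db = db, xmap = xmap)
}

# codons for one amino acid under the standard genetic code
codons_for <- function(aa, genetic_code = Biostrings::GENETIC_CODE) {
  names(genetic_code)[genetic_code == aa]
}

#' Sample reads of known provenance from a protein database
#'
#' Each read picks a source protein uniformly, picks a peptide window,
#' reverse-translates it with uniformly random synonymous codons (no
#' codon-usage model), truncates to the requested read length, applies
#' i.i.d. substitution errors at `nt_error_rate`, and reverse-complements
#' with probability `revcomp_probability`. Deterministic under the
#' configuration's seed (offset so the read stream is independent of
#' whether [generate_toy_cogdb()] ran in the same session).
#'
#' @param db A [cog_database()] whose proteins are all at least
#'   `ceiling(read_length_nt / 3)` residues long.
#' @param cfg A [simulation_config()].
#' @return List with `reads` (data frame `read_id`, `nt_sequence`,
#'   `quality`) and `truth` (data frame `read_id`, `source_protein_id`,
#'   `source_cog_id`, `source_categories`, `strand`,
#'   `nt_errors_introduced`).
#' @export
sample_reads <- function(db, cfg = simulation_config()) {
  stopifnot(inherits(db, "cog_database"), inherits(cfg, "simulation_config"))
  if (nrow(db$proteins) == 0L) stop("database is empty")
  aa_window <- as.integer(ceiling(cfg$read_length_nt / 3))
  if (any(nchar(db$proteins$aa_sequence) < aa_window)) {
    stop("read_length_nt requires proteins of at least ", aa_window, " residues")
  }
  set.seed(cfg$seed + 1L)
  bases <- c("A", "C", "G", "T")
  reads <- character(cfg$n_reads)
  truth <- data.frame(read_id = sprintf("read_%04d", seq_len(cfg$n_reads)),
                      source_protein_id = NA_character_,
                      source_cog_id = NA_character_,
                      source_categories = NA_character_,
                      strand = NA_character_,
                      nt_errors_introduced = NA_integer_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(cfg$n_reads)) {
    p <- db$proteins[sample.int(nrow(db$proteins), 1L), ]
    plen <- nchar(p$aa_sequence)
    start <- sample.int(plen - aa_window + 1L, 1L)
    window <- substr(p$aa_sequence, start, start + aa_window - 1L)
    codons <- vapply(strsplit(window, "")[[1]], function(a) {
      cand <- codons_for(a)
      cand[sample.int(length(cand), 1L)]
    }, "")
    nt <- strsplit(substr(paste(codons, collapse = ""), 1L,
                          cfg$read_length_nt), "")[[1]]
    err <- stats::runif(length(nt)) < cfg$nt_error_rate
    if (any(err)) {
      nt[err] <- vapply(nt[err], function(old) {
        sample(setdiff(bases, old), 1L)
      }, "")
    }
    seq_str <- paste(nt, collapse = "")
    strand <- if (stats::runif(1) < cfg$revcomp_probability) "-" else "+"
    if (strand == "-") {
      seq_str <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq_str)))
    }
    reads[i] <- seq_str
    truth$source_protein_id[i] <- p$protein_id
    truth$source_cog_id[i] <- p$cog_id
    truth$source_categories[i] <- p$categories
    truth$strand[i] <- strand
    truth$nt_errors_introduced[i] <- sum(err)
  }
  list(reads = data.frame(read_id = truth$read_id, nt_sequence = reads,
                          quality = NA_character_, stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate negative-control reads of i.i.d. random bases
#'
#' Such reads carry no planted signal and are expected to fall below the
#' e-value threshold of any search, populating the unassigned (true
#' negative) class of a benchmark comparison.
#'
#' @param n Number of reads.
#' @param read_length_nt Read length.
#' @param seed Integer RNG seed.
#' @param prefix Read id prefix.
#' @return Data frame `read_id`, `nt_sequence`, `quality`.
#' @export
random_reads <- function(n, read_length_nt = 150L, seed = 7L,
                         prefix = "random") {
  set.seed(as.integer(seed))
  data.frame(
    read_id = sprintf("%s_%04d", prefix, seq_len(n)),
    nt_sequence = vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), read_length_nt, replace = TRUE),
            collapse = "")
    }, ""),
    quality = NA_character_, stringsAsFactors = FALSE)
}
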
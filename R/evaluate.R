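#' Read-level confusion counts against a benchmark annotation
#'
#' Compares a tool's annotation of each read with a benchmark annotation of
#' the same reads in one namespace. With the default (lenient) convention a
#' read counts as a true positive when both label sets are non-empty and
#' intersect; `strict = TRUE` requires the sets to be equal. In both
#' conventions: tool non-empty with benchmark empty or non-matching is a
#' false positive; both empty is a true negative; tool empty with benchmark
#' non-empty is a false negative. Every read falls in exactly one cell, so
#' TP+FP+TN+FN equals the number of reads.
#'
#' @param tool,benchmark Annotation data frames covering the same read ids
#'   (columns as from [annotate_reads()]).
#' @param namespace One of `cog`, `category`, `kegg`, `pfam`, `go`, `seed`.
#' @param strict Require exact label-set equality for a true positive.
#' @return Object of class `"confusion_counts"`: list with `namespace`,
#'   `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(tool, benchmark, namespace, strict = FALSE) {
  namespace <- match.arg(tolower(namespace), annotation_namespaces())
  if (!setequal(tool$read_id, benchmark$read_id) ||
      anyDuplicated(tool$read_id) || anyDuplicated(benchmark$read_id)) {
    diff <- c(setdiff(tool$read_id, benchmark$read_id),
              setdiff(benchmark$read_id, tool$read_id))
    stop("tool and benchmark read ids differ: ",
         paste(unique(diff), collapse = ", "))
  }
  b <- benchmark[match(tool$read_id, benchmark$read_id), ]
  split_terms <- function(x) {
    lapply(strsplit(x, ";", fixed = TRUE), function(v) v[nzchar(v)])
  }
  tl <- split_terms(tool[[namespace]])
  bl <- split_terms(b[[namespace]])
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(tl)) {
    t_has <- length(tl[[i]]) > 0L
    b_has <- length(bl[[i]]) > 0L
    if (t_has && b_has) {
      match_ok <- if (strict) setequal(tl[[i]], bl[[i]])
        else length(intersect(tl[[i]], bl[[i]])) > 0L
      if (match_ok) tp <- tp + 1L else fp <- fp + 1L
    } else if (t_has) {
      fp <- fp + 1L
    } else if (b_has) {
      fn <- fn + 1L
    } else {
      tn <- tn + 1L
    }
  }
  structure(list(namespace = namespace, TP = tp, FP = fp, TN = tn, FN = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  pv <- predictive_values(x)
  cat(sprintf("%s: TP=%d FP=%d TN=%d FN=%d  PPV=%s NPV=%s\n", x$namespace,
              x$TP, x$FP, x$TN, x$FN,
              format(pv$ppv, digits = 4), format(pv$npv, digits = 4)))
  invisible(x)
}

#' Positive and negative predictive value
#'
#' `PPV = TP / (TP + FP)` and `NPV = TN / (TN + FN)`. A value whose
#' denominator is zero is undefined and reported as `NA` (a distinct
#' marker, not 0 or 1, so it cannot bias averages).
#'
#' @param counts A [confusion_counts()] object (or list with `TP`, `FP`,
#'   `TN`, `FN`).
#' @return List with `ppv` and `npv` (each numeric or `NA`).
#' @examples
#' predictive_values(list(TP = 3, FP = 1, TN = 4, FN = 1))  # 0.75, 0.8
#' @export
predictive_values <- function(counts) {
  ppv <- if (counts$TP + counts$FP > 0) counts$TP / (counts$TP + counts$FP)
    else NA_real_
  npv <- if (counts$TN + counts$FN > 0) counts$TN / (counts$TN + counts$FN)
    else NA_real_
  list(ppv = ppv, npv = npv)
}

#' Pearson correlation between two functional profiles
#'
#' Count vectors are built over the union of the two profiles' terms in the
#' given namespace (a term absent from one profile counts 0 there); the
#' p-value comes from the two-sided t-test for a correlation coefficient
#' with n-2 degrees of freedom.
#'
#' @param a,b [build_profile()] objects (or named lists of count vectors,
#'   as from [read_profile()]).
#' @param namespace Namespace to compare (e.g. `"cog"`, `"kegg"`).
#' @return List with `pearson_r` and `p_value`.
#' @export
profile_correlation <- function(a, b, namespace) {
  namespace <- match.arg(tolower(namespace), annotation_namespaces())
  get_counts <- function(p) {
    if (inherits(p, "functional_profile")) p$counts[[namespace]]
    else p[[namespace]]
  }
  ca <- get_counts(a)
  cb <- get_counts(b)
  terms <- union(names(ca), names(cb))
  if (length(terms) < 3L) {
    stop("need at least 3 terms in the union of the two profiles")
  }
  va <- ifelse(terms %in% names(ca), ca[terms], 0L)
  vb <- ifelse(terms %in% names(cb), cb[terms], 0L)
  va[is.na(va)] <- 0L
  vb[is.na(vb)] <- 0L
  if (stats::var(va) == 0 || stats::var(vb) == 0) {
    stop("zero variance in a profile count vector")
  }
  ct <- stats::cor.test(va, vb, method = "pearson", alternative = "two.sided")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value)
}
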
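#' Edge Correctness
#'
#' The fraction of reference parent-to-child edges that also appear, with
#' the same direction, in the inferred hierarchy:
#' \eqn{EC = |E_{ref} \cap E_{inf}| / |E_{ref}|}. A reversed edge does not
#' count; an edge whose endpoint is absent from the inferred hierarchy simply
#' cannot match (the denominator is always the reference edge count).
#'
#' @param ref,inf [hierarchy()] objects (reference and inferred).
#' @return a score in \eqn{[0, 1]}.
#' @export
edge_correctness <- function(ref, inf) {
  stopifnot(inherits(ref, "hierarchy"), inherits(inf, "hierarchy"))
  if (!nrow(ref$edges)) {
    stop("reference hierarchy has no edges", call. = FALSE)
  }
  key <- function(e) paste(e$parent, e$child, sep = "\r")
  mean(key(ref$edges) %in% key(inf$edges))
}

#' Ancestor Jaccard of a single term
#'
#' The Jaccard index of the proper-ancestor sets of term `x` in the
#' reference and inferred hierarchies,
#' \eqn{Jaccard(A(x_{ref}), A(x_{inf}))}. When `x` has no ancestors in
#' either hierarchy (a root in both) the quantity is undefined and `NA` is
#' returned; such terms are excluded from [ancestor_correctness()].
#'
#' @param ref,inf [hierarchy()] objects; `x` must be present in both.
#' @param x a term id.
#' @return a score in \eqn{[0, 1]}, or `NA` when both ancestor sets are empty.
#' @export
ancestor_jaccard <- function(ref, inf, x) {
  a_ref <- ancestors(ref, x)
  a_inf <- ancestors(inf, x)
  if (!length(a_ref) && !length(a_inf)) return(NA_real_)
  jaccard_index(a_ref, a_inf)
}

#' Ancestor Correctness
#'
#' The mean [ancestor_jaccard()] over the terms present in both
#' hierarchies, excluding terms that are roots in both (their ancestor
#' Jaccard is undefined). Unlike edge correctness, this credits correctly
#' recovered ancestry even when terms are separated by several taxonomic
#' links.
#'
#' @param ref,inf [hierarchy()] objects sharing at least one term that has
#'   an ancestor in at least one of them.
#' @return a score in \eqn{[0, 1]}.
#' @export
ancestor_correctness <- function(ref, inf) {
  aj <- shared_ancestor_table(ref, inf)$aj
  aj <- aj[!is.na(aj)]
  if (!length(aj)) {
    stop("no shared term has ancestors in either hierarchy", call. = FALSE)
  }
  mean(aj)
}

# per-shared-term ancestor statistics (internal)
shared_ancestor_table <- function(ref, inf) {
  stopifnot(inherits(ref, "hierarchy"), inherits(inf, "hierarchy"))
  shared <- intersect(ref$nodes$id, inf$nodes$id)
  if (!length(shared)) {
    stop("hierarchies share no terms", call. = FALSE)
  }
  a_ref <- ancestor_sets(ref)
  a_inf <- ancestor_sets(inf)
  n_ref <- lengths(a_ref[shared])
  n_inf <- lengths(a_inf[shared])
  n_common <- mapply(function(r, i) length(intersect(r, i)),
                     a_ref[shared], a_inf[shared])
  data.frame(
    term = shared,
    n_ref = n_ref, n_inf = n_inf, n_common = n_common,
    aj = ifelse(n_ref + n_inf == 0, NA_real_,
                n_common / (n_ref + n_inf - n_common)),
    hp = ifelse(n_inf > 0, n_common / n_inf, NA_real_),
    hr = ifelse(n_ref > 0, n_common / n_ref, NA_real_),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Ancestor Precision, Recall and F
#'
#' Adapts hierarchical precision and recall to disease hierarchies. For a
#' shared term `x` with ancestor sets \eqn{A(x_{ref})} and \eqn{A(x_{inf})}:
#' \deqn{HP(x) = |A(x_{ref}) \cap A(x_{inf})| / |A(x_{inf})|}
#' \deqn{HR(x) = |A(x_{ref}) \cap A(x_{inf})| / |A(x_{ref})|}
#' Ancestor precision `ap` is the mean of HP over terms with a non-empty
#' inferred ancestor set, ancestor recall `ar` the mean of HR over terms with
#' a non-empty reference ancestor set (per-term ratios with a zero
#' denominator are undefined and skipped). The F score is the harmonic mean
#' of the two averages, \eqn{F = 2 \cdot AP \cdot AR / (AP + AR)} (0 when
#' both are 0). Per-term HP/HR/F values are returned alongside for users who
#' prefer aggregating F per term.
#'
#' @param ref,inf [hierarchy()] objects sharing terms.
#' @return a list with `ap`, `ar`, `f`, and a `per_term` data frame of
#'   per-term `hp`, `hr` and `f` values.
#' @export
ancestor_precision_recall <- function(ref, inf) {
  tab <- shared_ancestor_table(ref, inf)
  hp <- tab$hp[!is.na(tab$hp)]
  hr <- tab$hr[!is.na(tab$hr)]
  if (!length(hp) || !length(hr)) {
    stop("no shared term has ancestors on the required side", call. = FALSE)
  }
  ap <- mean(hp)
  ar <- mean(hr)
  f <- if (ap + ar == 0) 0 else 2 * ap * ar / (ap + ar)
  tab$f <- ifelse(!is.na(tab$hp) & !is.na(tab$hr) & (tab$hp + tab$hr) > 0,
                  2 * tab$hp * tab$hr / (tab$hp + tab$hr),
                  ifelse(!is.na(tab$hp) & !is.na(tab$hr), 0, NA_real_))
  list(ap = ap, ar = ar, f = f,
       per_term = tab[, c("term", "hp", "hr", "f")])
}

#' Score an inferred hierarchy against a reference
#'
#' Computes all four hierarchy-comparison metrics in one call:
#' [edge_correctness()] (EC), [ancestor_correctness()] (AC), and
#' [ancestor_precision_recall()] (AP, AR and their harmonic mean F),
#' together with bookkeeping counts. Terms present in only one of the two
#' hierarchies are reported in a log message and simply cannot contribute
#' matches.
#'
#' @param ref,inf [hierarchy()] objects with at least one shared term.
#' @param quiet suppress the log message about unshared terms.
#' @return an object of class `evaluation_report`: a list with fields `ec`,
#'   `ac`, `ap`, `ar`, `f`, `n_shared_terms`, `n_ref_edges` and the
#'   `per_term` table from [ancestor_precision_recall()].
#' @export
evaluate_hierarchy <- function(ref, inf, quiet = FALSE) {
  stopifnot(inherits(ref, "hierarchy"), inherits(inf, "hierarchy"))
  shared <- intersect(ref$nodes$id, inf$nodes$id)
  if (!length(shared)) stop("hierarchies share no terms", call. = FALSE)
  only_ref <- nrow(ref$nodes) - length(shared)
  only_inf <- nrow(inf$nodes) - length(shared)
  if (!quiet && (only_ref || only_inf)) {
    message(sprintf("%d term(s) only in reference, %d only in inferred hierarchy",
                    only_ref, only_inf))
  }
  apr <- ancestor_precision_recall(ref, inf)
  report <- list(ec = edge_correctness(ref, inf),
                 ac = ancestor_correctness(ref, inf),
                 ap = apr$ap, ar = apr$ar, f = apr$f,
                 n_shared_terms = length(shared),
                 n_ref_edges = nrow(ref$edges),
                 per_term = apr$per_term)
  class(report) <- "evaluation_report"
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Hierarchy evaluation\n")
  cat(sprintf("  shared terms: %d   reference edges: %d\n",
              x$n_shared_terms, x$n_ref_edges))
  cat(sprintf("  EC %.3f  AC %.3f  AP %.3f  AR %.3f  F %.3f\n",
              x$ec, x$ac, x$ap, x$ar, x$f))
  invisible(x)
}
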
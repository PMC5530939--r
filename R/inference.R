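#' Read a citation-count table
#'
#' Citation counts (e.g. the number of disease-related PubMed articles per
#' term) drive both the promotion step of Parent Promotion and the rooting
#' of the minimum-weight spanning tree: a higher count is taken as evidence
#' that a term is the more general one.
#'
#' @param path a TSV of `disease_id<TAB>count` rows.
#' @return a named numeric vector of non-negative counts.
#' @export
read_citations <- function(path) {
  df <- read_tsv_fields(path, 2L, "citation")
  names(df) <- c("disease_id", "count")
  counts <- suppressWarnings(as.numeric(df$count))
  if (anyNA(counts) || any(counts < 0)) {
    stop(sprintf("invalid citation count '%s' in %s",
                 df$count[is.na(counts) | counts < 0][1L], path), call. = FALSE)
  }
  if (anyDuplicated(df$disease_id)) {
    stop(sprintf("duplicate citation entry for disease '%s'",
                 df$disease_id[duplicated(df$disease_id)][1L]), call. = FALSE)
  }
  stats::setNames(counts, df$disease_id)
}

#' Write a citation table to TSV
#' @param citations named numeric vector of counts.
#' @param path output file.
#' @export
write_citations <- function(citations, path) {
  writeLines(c("#disease_id\tcount",
               paste(names(citations), format(citations, scientific = FALSE,
                                              trim = TRUE), sep = "\t")), path)
  invisible(path)
}

check_citations <- function(citations, labels) {
  if (is.null(names(citations))) {
    stop("citation counts must be a named vector", call. = FALSE)
  }
  missing <- setdiff(labels, names(citations))
  if (length(missing)) {
    stop(sprintf("missing citation count for disease '%s'", missing[1L]),
         call. = FALSE)
  }
  if (anyNA(citations[labels]) || any(citations[labels] < 0)) {
    stop("citation counts must be non-negative numbers", call. = FALSE)
  }
  invisible(citations)
}

#' Complete-linkage hierarchical clustering of diseases
#'
#' Agglomeratively clusters diseases on a distance matrix (typically
#' `to_distance(build_similarity_matrix(...))`), with inter-cluster distance
#' defined as the maximum pairwise distance. This is a thin wrapper around
#' [stats::hclust()] with `method = "complete"`, whose merge heights are
#' non-decreasing; the dendrogram's internal nodes are unnamed clusters of
#' diseases that [parent_promotion()] subsequently resolves to single terms.
#'
#' @param d a labelled symmetric distance matrix with zero diagonal and at
#'   least two diseases.
#' @return an [stats::hclust] object.
#' @export
complete_linkage <- function(d) {
  check_square_matrix(d)
  if (nrow(d) < 2L) stop("need at least two diseases to cluster", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  stats::hclust(stats::as.dist(d), method = "complete")
}

# resolve citation contest: returns c(parent, child); larger count wins,
# ties broken by the lexicographically smaller id becoming the parent
promote <- function(a, b, citations) {
  ca <- citations[[a]]; cb <- citations[[b]]
  if (ca > cb) c(a, b)
  else if (cb > ca) c(b, a)
  else if (lex_min(c(a, b)) == a) c(a, b)
  else c(b, a)
}

#' Parent Promotion: dendrogram to rooted disease tree
#'
#' Converts a complete-linkage dendrogram into a hierarchy with a single
#' disease at every node. Working bottom-up through the merges, each cluster
#' carries one representative - its most recently promoted disease (a
#' singleton represents itself). At every binary merge the two
#' representatives' citation counts are compared; the more-cited disease is
#' promoted to become the parent of the other representative and represents
#' the merged cluster. Once a disease has been made a child it never competes
#' again, so earlier subtrees are carried along intact. The representative of
#' the final merge is the root.
#'
#' The output always has exactly the input diseases as nodes, `n - 1` edges,
#' a single root, and satisfies `citations[parent] >= citations[child]` on
#' every edge (equality only when the tie rule fired; ties are broken by the
#' lexicographically smaller id winning).
#'
#' @param dendrogram an [stats::hclust] object from [complete_linkage()].
#' @param citations named numeric vector covering every leaf.
#' @return a [hierarchy()] tree with attribute `root`.
#' @export
parent_promotion <- function(dendrogram, citations) {
  stopifnot(inherits(dendrogram, "hclust"))
  labels <- dendrogram$labels
  if (is.null(labels)) stop("dendrogram has no leaf labels", call. = FALSE)
  check_citations(citations, labels)
  n <- length(labels)
  merges <- dendrogram$merge
  rep_of <- character(n - 1L)           # representative of each merge's cluster
  parent_edges <- matrix(character(), 0L, 2L)
  for (i in seq_len(n - 1L)) {
    resolve <- function(k) if (k < 0L) labels[-k] else rep_of[k]
    a <- resolve(merges[i, 1L])
    b <- resolve(merges[i, 2L])
    pc <- promote(a, b, citations)
    parent_edges <- rbind(parent_edges, pc)
    rep_of[i] <- pc[1L]
  }
  edges <- data.frame(parent = parent_edges[, 1L], child = parent_edges[, 2L],
                      stringsAsFactors = FALSE)
  out <- hierarchy(labels, edges)
  attr(out, "root") <- rep_of[n - 1L]
  attr(out, "method") <- "parent_promotion"
  out
}

#' Rooted minimum-weight spanning tree inference
#'
#' Builds the spanning tree of the complete disease graph minimising total
#' edge weight, where the weight of a pair is its distance
#' `1 - disease_sim`, so the minimum-weight tree connects all diseases
#' through their highest gene-set similarities. Construction is Kruskal's
#' algorithm with edges processed in the deterministic order
#' (weight, smaller id, larger id), which pins down the result when many
#' pairs tie (common when diseases share no genes, giving weight 1). The
#' unrooted tree is then rooted at the disease with the highest citation
#' count and every edge oriented away from the root.
#'
#' @param d a labelled symmetric distance matrix (at least two diseases).
#' @param citations named numeric vector covering all diseases.
#' @return a [hierarchy()] tree with attribute `root`.
#' @export
mwst_infer <- function(d, citations) {
  check_square_matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least two diseases", call. = FALSE)
  labels <- rownames(d)
  check_citations(citations, labels)
  ij <- which(upper.tri(d), arr.ind = TRUE)
  la <- labels[ij[, 1L]]; lb <- labels[ij[, 2L]]
  swap <- lb < la
  lo <- ifelse(swap, lb, la); hi <- ifelse(swap, la, lb)
  ord <- order(d[ij], lo, hi, method = "radix")
  # union-find over label indices
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  tree_a <- character(n - 1L); tree_b <- character(n - 1L)
  taken <- 0L
  for (e in ord) {
    ia <- find(match(lo[e], labels)); ib <- find(match(hi[e], labels))
    if (ia != ib) {
      parent[ia] <- ib
      taken <- taken + 1L
      tree_a[taken] <- lo[e]; tree_b[taken] <- hi[e]
      if (taken == n - 1L) break
    }
  }
  root <- labels[order(-citations[labels], labels, method = "radix")][1L]
  # orient away from the root by breadth-first traversal
  adj <- split(c(tree_b, tree_a), c(tree_a, tree_b))
  seen <- stats::setNames(logical(n), labels)
  seen[root] <- TRUE
  frontier <- root
  ep <- character(n - 1L); ec <- character(n - 1L); k <- 0L
  while (length(frontier)) {
    nxt <- character()
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (!seen[[w]]) {
          seen[w] <- TRUE
          k <- k + 1L
          ep[k] <- v; ec[k] <- w
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  out <- hierarchy(labels, data.frame(parent = ep, child = ec,
                                      stringsAsFactors = FALSE))
  attr(out, "root") <- root
  attr(out, "method") <- "mwst"
  attr(out, "total_weight") <- sum(d[cbind(match(tree_a, labels),
                                           match(tree_b, labels))])
  out
}

#' Infer a disease tree from associations and citations
#'
#' Composes the pipeline similarity -> distance -> inference method. With
#' `method = "parent_promotion"` (alias `"pp"`) the distance matrix is
#' clustered by [complete_linkage()] and resolved by [parent_promotion()];
#' with `method = "mwst"` the rooted minimum-weight spanning tree is built
#' directly.
#'
#' @param method `"parent_promotion"` (or `"pp"`) or `"mwst"`.
#' @param table an [association_table()].
#' @param diseases ordered disease ids to include (all must have genes).
#' @param citations named numeric vector covering `diseases`.
#' @param quiet suppress the log message.
#' @return a [hierarchy()] tree with attribute `root`.
#' @export
infer <- function(method = c("parent_promotion", "pp", "mwst"), table,
                  diseases, citations, quiet = FALSE) {
  method <- match.arg(method)
  if (method == "pp") method <- "parent_promotion"
  sim <- build_similarity_matrix(table, diseases)
  d <- to_distance(sim)
  out <- switch(method,
    parent_promotion = parent_promotion(complete_linkage(d), citations),
    mwst = mwst_infer(d, citations))
  if (!quiet) {
    message(sprintf("inferred %s tree over %d diseases (root: %s)",
                    method, length(diseases), attr(out, "root")))
  }
  out
}
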
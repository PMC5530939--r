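#' Configuration for the synthetic-data generator
#'
#' Bundles the knobs of the generative model used to emulate the structure
#' the inference methods assume: a rooted taxonomy, gene sets that children
#' partially inherit from their parents (so gene-set Jaccard carries the
#' clustering signal), and citation counts that decay with depth (so more
#' general terms are more cited, carrying the promotion signal).
#'
#' Each generator stage draws from its own stream seeded deterministically
#' from `seed` (taxonomy: `seed`, associations: `seed + 1`, citations:
#' `seed + 2`), so stages are individually reproducible.
#'
#' @param n_terms number of disease terms (>= 2).
#' @param max_children maximum children per node in the taxonomy (>= 2).
#' @param genes_per_term novel genes introduced at each node (>= 1).
#' @param inherit_fraction fraction of the parent's gene set copied to each
#'   child, in \eqn{[0, 1]}.
#' @param noise_swap_rate fraction of association pairs reassigned to
#'   uniformly random diseases, in \eqn{[0, 1]}.
#' @param citation_base citation count of the root (positive integer).
#' @param citation_decay multiplicative decay of counts per depth level,
#'   in \eqn{(0, 1)}.
#' @param seed integer seed.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_terms = 50L, max_children = 3L,
                             genes_per_term = 5L, inherit_fraction = 0.7,
                             noise_swap_rate = 0, citation_base = 10000L,
                             citation_decay = 0.5, seed = 1L) {
  stopifnot(n_terms >= 2, max_children >= 2, genes_per_term >= 1,
            inherit_fraction >= 0, inherit_fraction <= 1,
            noise_swap_rate >= 0, noise_swap_rate <= 1,
            citation_base >= 1,
            citation_decay > 0, citation_decay < 1)
  structure(list(n_terms = as.integer(n_terms),
                 max_children = as.integer(max_children),
                 genes_per_term = as.integer(genes_per_term),
                 inherit_fraction = inherit_fraction,
                 noise_swap_rate = noise_swap_rate,
                 citation_base = as.integer(citation_base),
                 citation_decay = citation_decay,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# random attachment tree shared by generate_taxonomy and the fixtures;
# assumes the RNG stream is already seeded
sample_tree <- function(n, max_children) {
  parent <- integer(n)
  out_deg <- integer(n)
  for (i in seq_len(n)[-1L]) {
    elig <- which(out_deg[seq_len(i - 1L)] < max_children)
    p <- if (length(elig) == 1L) elig else sample(elig, 1L)
    parent[i] <- p
    out_deg[p] <- out_deg[p] + 1L
  }
  parent
}

#' Generate a random rooted taxonomy
#'
#' Draws a random rooted tree with `n_terms` nodes by sequential attachment:
#' each new node picks a uniformly random parent among earlier nodes that
#' still have fewer than `max_children` children. Node ids are `D0001`,
#' `D0002`, ... with `D0001` the root. Bit-reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return a [hierarchy()] tree with attribute `root`.
#' @export
generate_taxonomy <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_terms
  ids <- sprintf("D%04d", seq_len(n))
  parent <- sample_tree(n, config$max_children)
  h <- hierarchy(ids, data.frame(parent = ids[parent[-1L]],
                                 child = ids[-1L],
                                 stringsAsFactors = FALSE))
  attr(h, "root") <- ids[1L]
  h
}

# depth of every node below the (single) root of a tree (internal)
node_depths <- function(h) {
  r <- roots(h)
  stopifnot(length(r) == 1L)
  parent_of <- stats::setNames(h$edges$parent, h$edges$child)
  ord <- topological_sort(h)
  depth <- stats::setNames(integer(length(ord)), ord)
  for (v in ord) {
    if (v != r) depth[v] <- depth[[parent_of[[v]]]] + 1L
  }
  depth[h$nodes$id]
}

#' Generate disease-gene associations along a taxonomy
#'
#' The root receives `genes_per_term` fresh genes; each child's gene set is
#' a sample of `round(inherit_fraction * |parent set|)` parental genes plus
#' `genes_per_term` fresh ones, so gene-set similarity decays with tree
#' distance. Finally a fraction `noise_swap_rate` of all (disease, gene)
#' pairs is reassigned to uniformly random diseases (see
#' [perturb_associations()]); every disease always retains at least one
#' gene. Bit-reproducible from `config$seed`.
#'
#' @param h a rooted tree from [generate_taxonomy()].
#' @param config a [synthetic_config()].
#' @return an [association_table()].
#' @export
generate_associations <- function(h, config) {
  stopifnot(inherits(h, "hierarchy"), inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  ord <- topological_sort(h)
  parent_of <- stats::setNames(h$edges$parent, h$edges$child)
  sets <- vector("list", length(ord))
  names(sets) <- ord
  counter <- 0L
  fresh <- function(k) {
    out <- sprintf("G%06d", counter + seq_len(k))
    counter <<- counter + k
    out
  }
  for (v in ord) {
    p <- parent_of[v]
    inherited <- if (is.na(p)) character() else {
      ps <- sets[[p]]
      k <- round(config$inherit_fraction * length(ps))
      if (k > 0L) sample(ps, k) else character()
    }
    sets[[v]] <- c(inherited, fresh(config$genes_per_term))
  }
  tab <- association_table(data.frame(
    disease_id = rep(names(sets), lengths(sets)),
    gene_id = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE))
  if (config$noise_swap_rate > 0) {
    tab <- perturb_associations(tab, config$noise_swap_rate)
  }
  tab
}

#' Randomly reassign a fraction of association pairs
#'
#' The noise model of the generator, exposed for data-quantity experiments:
#' `rate` of the (disease, gene) pairs are picked at random and reassigned
#' to uniformly random diseases in the table. A pair is only moved when its
#' current disease keeps at least one gene, so no disease ever ends up
#' geneless; a reassignment that duplicates an existing pair collapses into
#' it.
#'
#' @param table an [association_table()].
#' @param rate fraction of pairs to reassign, in \eqn{[0, 1]}.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return a perturbed [association_table()].
#' @export
perturb_associations <- function(table, rate, seed = NULL) {
  stopifnot(inherits(table, "association_table"), rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(table)
  n_swap <- round(rate * n)
  if (n_swap == 0L) return(table)
  diseases <- unique(table$disease_id)
  counts <- table(table$disease_id)
  disease <- table$disease_id
  gene <- table$gene_id
  idx <- sample(n, n_swap)
  for (i in idx) {
    from <- disease[i]
    if (counts[[from]] < 2L) next
    to <- sample(diseases, 1L)
    if (to == from) next
    counts[from] <- counts[[from]] - 1L
    counts[to] <- counts[[to]] + 1L
    disease[i] <- to
  }
  association_table(data.frame(disease_id = disease, gene_id = gene,
                               stringsAsFactors = FALSE))
}

#' Generate citation counts that decay with depth
#'
#' Emulates the empirical tendency of general disease terms to accumulate
#' more literature than specific ones: a node at depth \eqn{k} receives
#' `round(citation_base * citation_decay^k)` minus a random jitter bounded
#' so that counts never reorder across adjacent depths. Counts therefore
#' decrease strictly along every root-to-leaf path and the root holds the
#' unique maximum. Errors if `citation_base` is too small for the tree's
#' depth to keep the separation strict.
#'
#' @param h a rooted [hierarchy()] tree.
#' @param config a [synthetic_config()].
#' @return a named numeric vector of counts.
#' @export
generate_citations <- function(h, config) {
  stopifnot(inherits(h, "hierarchy"), inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L)
  depth <- node_depths(h)
  dmax <- max(depth)
  base <- round(config$citation_base * config$citation_decay ^ (0:(dmax + 1L)))
  gap <- base[-length(base)] - base[-1L]
  if (any(gap[seq_len(dmax + 1L)] < 2L)) {
    stop("citation_base too small to keep counts strictly decreasing with depth",
         call. = FALSE)
  }
  jmax <- pmax(0L, gap - 1L)
  counts <- vapply(h$nodes$id, function(v) {
    k <- depth[[v]]
    j <- jmax[k + 1L]
    jitter <- if (k == 0L || j == 0L) 0L else sample(0:j, 1L)
    base[k + 1L] - jitter
  }, numeric(1L))
  counts
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running the three generator stages in order.
#'
#' @param config a [synthetic_config()].
#' @return a list with elements `taxonomy` ([hierarchy()]), `associations`
#'   ([association_table()]) and `citations` (named numeric vector).
#' @export
generate_dataset <- function(config) {
  taxonomy <- generate_taxonomy(config)
  associations <- generate_associations(taxonomy, config)
  citations <- generate_citations(taxonomy, config)
  list(taxonomy = taxonomy, associations = associations,
       citations = citations)
}

#' Separable fixture with guaranteed exact recovery
#'
#' Builds a noise-free dataset on which Parent Promotion provably
#' reproduces the generating tree edge for edge (EC = 1). The taxonomy is a
#' random attachment tree; the gene sets are constructed so that the
#' disease-gene Jaccard distances form an exact ultrametric whose dendrogram
#' is a specific plan: each parent's singleton cluster absorbs its
#' children's (already fully formed) subtree clusters one at a time, at
#' strictly increasing heights along every dendrogram path. Complete-linkage
#' clustering reproduces that dendrogram exactly, and because citation
#' counts decrease strictly with depth, every promotion contest is won by
#' the parent - so the inferred tree equals the generating tree.
#'
#' Concretely, each planned merge event owns one shared "path gene"; a
#' disease's gene set is the path genes of all events above it in the
#' planned dendrogram, padded with private genes to a common set size `S`.
#' Two diseases then share exactly the path genes of the events above their
#' lowest common merge, giving Jaccard `C / (2S - C)` with `C` the count of
#' shared events - strictly increasing along every dendrogram path.
#'
#' @param n_terms number of disease terms (>= 2).
#' @param seed integer seed.
#' @param max_children maximum children per node in the random tree.
#' @return a list with `taxonomy`, `associations`, `citations`.
#' @export
make_separable_fixture <- function(n_terms, seed = 1L, max_children = 3L) {
  stopifnot(n_terms >= 2)
  set.seed(seed)
  n <- as.integer(n_terms)
  ids <- sprintf("D%04d", seq_len(n))
  parent <- sample_tree(n, max_children)
  children <- lapply(seq_len(n), function(i) which(parent == i))

  # Dendrogram plan. For internal node p with children c_1..c_m, the cluster
  # of p forms by joining dend(sub(c_1)), ..., dend(sub(c_m)) onto {p} in
  # order; event (p, i) is the i-th join. The parent event of (p, i) is
  # (p, i+1), except the last, whose parent is the event joining sub(p)
  # into p's own parent. Event depths (root event = 1) give the shared-gene
  # counts C: deeper events share more genes.
  event_id <- matrix(0L, n, max(1L, max(lengths(children))))
  n_events <- 0L
  for (p in seq_len(n)) {
    for (i in seq_along(children[[p]])) {
      n_events <- n_events + 1L
      event_id[p, i] <- n_events
    }
  }
  # parent event pointers
  join_event_of <- integer(n)   # event that joins sub(v) into v's parent
  for (q in seq_len(n)) {
    for (i in seq_along(children[[q]])) {
      join_event_of[children[[q]][i]] <- event_id[q, i]
    }
  }
  event_parent <- integer(n_events)
  for (p in seq_len(n)) {
    m <- length(children[[p]])
    if (!m) next
    for (i in seq_len(m)) {
      event_parent[event_id[p, i]] <-
        if (i < m) event_id[p, i + 1L]
        else if (p == 1L) 0L
        else join_event_of[p]
    }
  }
  # first event above each leaf of the dendrogram (= each disease term)
  first_event <- ifelse(lengths(children) > 0L,
                        event_id[cbind(seq_len(n), 1L)],
                        join_event_of)
  # gene set of term v: one gene per event on the path first_event(v) -> root
  event_path <- function(e) {
    out <- integer()
    while (e != 0L) { out <- c(out, e); e <- event_parent[e] }
    out
  }
  paths <- lapply(first_event, event_path)
  s_max <- max(lengths(paths)) + 1L   # pad all sets to equal size
  records <- do.call(rbind, lapply(seq_len(n), function(v) {
    shared <- sprintf("E%05d", paths[[v]])
    private <- sprintf("P%s_%02d", ids[v], seq_len(s_max - length(shared)))
    data.frame(disease_id = ids[v], gene_id = c(shared, private),
               stringsAsFactors = FALSE)
  }))
  associations <- association_table(records)

  # citations: strictly decreasing with depth, all distinct
  depth <- integer(n)
  for (i in seq_len(n)[-1L]) depth[i] <- depth[parent[i]] + 1L
  counts <- (max(depth) - depth + 1L) * (n + 1L) - seq_len(n)
  citations <- stats::setNames(as.numeric(counts), ids)

  taxonomy <- hierarchy(ids, data.frame(parent = ids[parent[-1L]],
                                        child = ids[-1L],
                                        stringsAsFactors = FALSE))
  attr(taxonomy, "root") <- ids[1L]
  list(taxonomy = taxonomy, associations = associations,
       citations = citations)
}

#' Write a synthetic dataset to a directory
#'
#' Emits the three TSV artifacts (`taxonomy_edges.tsv` +
#' `taxonomy_nodes.tsv`, `associations.tsv`, `citations.tsv`) in the
#' package's interchange formats.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @return the list from [generate_dataset()], invisibly.
#' @export
write_synthetic_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data <- generate_dataset(config)
  write_hierarchy(data$taxonomy,
                  file.path(out_dir, "taxonomy_edges.tsv"),
                  file.path(out_dir, "taxonomy_nodes.tsv"),
                  comments = sprintf("diseasetree simulate seed=%d n_terms=%d",
                                     config$seed, config$n_terms))
  write_associations(data$associations, file.path(out_dir, "associations.tsv"))
  write_citations(data$citations, file.path(out_dir, "citations.tsv"))
  invisible(data)
}
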
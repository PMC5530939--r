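#' Read an OBO ontology as a disease hierarchy
#'
#' Parses OBO 1.2-style `[Term]` stanzas, keeping the tags `id`, `name`,
#' `is_a`, `synonym` and `is_obsolete`. Each `child is_a parent` assertion
#' becomes a parent-to-child edge (direction inverted). Obsolete terms are
#' dropped entirely; relationship types other than `is_a` are ignored.
#' Synonym strings are retained in a side map attached as the `synonyms`
#' attribute (id -> character vector), for users performing their own
#' vocabulary mapping.
#'
#' @param path an OBO flat file.
#' @return a [hierarchy()]; errors if an `is_a` target is undeclared (or
#'   obsolete) or if the `is_a` graph contains a cycle.
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop(sprintf("OBO file not found: %s", path), call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  stanza_starts <- which(lines == "[Term]")
  any_stanza <- grep("^\\[.*\\]$", lines)
  ids <- character(); nms <- character(); obsolete <- logical()
  parents <- list(); synonyms <- list()
  for (s in stanza_starts) {
    nxt <- any_stanza[any_stanza > s]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[(s + 1L):end]
    tagval <- function(tag) {
      v <- block[startsWith(block, paste0(tag, ":"))]
      trimws(sub(paste0("^", tag, ":"), "", v))
    }
    id <- tagval("id")[1L]
    if (is.na(id) || !nzchar(id)) next
    nm <- tagval("name")[1L]
    isa <- tagval("is_a")
    # strip trailing "! comment" annotations, keep the target id
    isa <- trimws(sub("!.*$", "", isa))
    isa <- vapply(strsplit(isa, "[[:space:]]+"), `[`, character(1L), 1L)
    syn_raw <- tagval("synonym")
    syn <- regmatches(syn_raw, regexpr('"[^"]*"', syn_raw))
    syn <- gsub('"', "", syn)
    obs <- any(grepl("^true", tagval("is_obsolete")))
    ids <- c(ids, id); nms <- c(nms, if (is.na(nm)) id else nm)
    obsolete <- c(obsolete, obs)
    parents[[id]] <- isa[!is.na(isa) & nzchar(isa)]
    synonyms[[id]] <- syn
  }
  keep <- !obsolete & !duplicated(ids)
  ids_live <- ids[keep]
  edges <- do.call(rbind, lapply(ids_live, function(id) {
    ps <- parents[[id]]
    if (!length(ps)) return(NULL)
    data.frame(parent = ps, child = id, stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(parent = character(), child = character())
  }
  undeclared <- setdiff(edges$parent, ids_live)
  if (length(undeclared)) {
    stop(sprintf("is_a references undeclared or obsolete term '%s'",
                 undeclared[1L]), call. = FALSE)
  }
  h <- hierarchy(data.frame(id = ids_live, name = nms[keep],
                            stringsAsFactors = FALSE), edges)
  attr(h, "synonyms") <- synonyms[ids_live]
  h
}

#' Read a MeSH-style tree-number table as a hierarchy
#'
#' MeSH addresses terms by dotted tree numbers (e.g. `C08.381.742`); a term
#' name may occupy several positions in the forest. The input is a normalised
#' two-column TSV `term_name<TAB>tree_number`, one row per position. Each
#' distinct name becomes one node (positions with the same name are merged,
#' so the forest of trees becomes a DAG), and each row whose tree-number
#' prefix (dropping the last dotted component) belongs to another row
#' contributes a parent-to-child edge between the owning names. Rows whose
#' prefix has no owner become roots. A merge that would create a self-loop
#' (a name appearing as its own ancestor elsewhere) drops that edge with a
#' warning.
#'
#' @param path a TSV of `(term_name, tree_number)` rows.
#' @return a [hierarchy()] whose node ids are the term names.
#' @export
read_mesh_trees <- function(path) {
  df <- read_tsv_fields(path, 2L, "MeSH tree")
  names(df) <- c("term_name", "tree_number")
  if (!nrow(df)) return(hierarchy(character()))
  tn <- trimws(df$tree_number)
  ok <- grepl("^[^.[:space:]]+(\\.[^.[:space:]]+)*$", tn)
  if (any(!ok)) {
    stop(sprintf("malformed tree number '%s' (empty component)", tn[!ok][1L]),
         call. = FALSE)
  }
  if (anyDuplicated(tn)) {
    dup <- tn[duplicated(tn)][1L]
    if (length(unique(df$term_name[tn == dup])) > 1L) {
      stop(sprintf("tree number '%s' assigned to multiple names", dup),
           call. = FALSE)
    }
  }
  owner <- df$term_name[!duplicated(tn)]
  names(owner) <- tn[!duplicated(tn)]
  prefix <- sub("\\.[^.]+$", "", tn)
  has_parent <- grepl(".", tn, fixed = TRUE) & prefix %in% names(owner)
  edges <- data.frame(parent = unname(owner[prefix[has_parent]]),
                      child = df$term_name[has_parent],
                      stringsAsFactors = FALSE)
  loops <- edges$parent == edges$child
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop edge(s) created by merging repeated name '%s'",
                    sum(loops), edges$parent[loops][1L]), call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  hierarchy(unique(df$term_name), unique(edges))
}

#' Prune terms without gene annotations, preserving ancestry
#'
#' Diseases for which no associated gene is known carry no signal for
#' similarity-based inference and are excluded from the reference. Removing
#' them can disconnect the hierarchy, so each retained node is reconnected to
#' its nearest retained proper ancestors: an edge `(p, x)` is kept exactly
#' when some parent path from `p` down to `x` passes through deleted nodes
#' only. This closure handles chains of consecutively deleted nodes, is
#' idempotent, and preserves ancestor/descendant reachability restricted to
#' the retained nodes. Retained descendants of deleted roots become roots.
#'
#' @param h a [hierarchy()].
#' @param table an [association_table()]; nodes of `h` whose id has at least
#'   one associated gene are retained.
#' @param quiet suppress the pruning summary message.
#' @return the pruned, reconnected [hierarchy()] (possibly empty).
#' @export
prune_and_reconnect <- function(h, table, quiet = FALSE) {
  stopifnot(inherits(h, "hierarchy"), inherits(table, "association_table"))
  retained <- h$nodes$id %in% unique(table$disease_id)
  names(retained) <- h$nodes$id
  ord <- topological_sort(h)
  parents <- split(h$edges$parent, h$edges$child)
  # nearest retained proper ancestors, computed parents-first
  nra <- vector("list", length(ord))
  names(nra) <- ord
  for (v in ord) {
    ps <- parents[[v]]
    if (is.null(ps)) {
      nra[[v]] <- character()
    } else {
      nra[[v]] <- unique(unlist(
        lapply(ps, function(p) if (retained[[p]]) p else nra[[p]]),
        use.names = FALSE))
    }
  }
  keep_ids <- h$nodes$id[retained]
  edges <- do.call(rbind, lapply(keep_ids, function(v) {
    ps <- nra[[v]]
    if (!length(ps)) return(NULL)
    data.frame(parent = ps, child = v, stringsAsFactors = FALSE)
  }))
  if (!quiet) {
    message(sprintf("pruned %d of %d terms without gene annotations",
                    sum(!retained), length(retained)))
  }
  hierarchy(h$nodes[retained, , drop = FALSE], edges)
}

#' Extract the sub-hierarchy rooted at a named term
#'
#' Returns the induced sub-DAG on a node and all of its descendants,
#' mirroring the extraction of disease subnetworks (e.g. cardiovascular or
#' nervous-system disease) from a full ontology. Name matching is exact and
#' case-sensitive. If the root has fewer than `min_descendants` descendants
#' a size error is raised carrying the actual count (condition field
#' `count`), so callers scanning many candidate roots can filter cheaply.
#'
#' @param h a [hierarchy()].
#' @param root_name the exact `name` of the desired root node.
#' @param min_descendants minimum number of proper descendants required.
#' @return a [hierarchy()] with attribute `root`; always weakly connected.
#' @export
extract_subnetwork <- function(h, root_name, min_descendants = 0L) {
  stopifnot(inherits(h, "hierarchy"))
  hit <- h$nodes$id[h$nodes$name == root_name]
  if (!length(hit)) {
    stop(sprintf("no node named '%s'", root_name), call. = FALSE)
  }
  if (length(hit) > 1L) {
    stop(sprintf("node name '%s' is ambiguous (%d matches)", root_name,
                 length(hit)), call. = FALSE)
  }
  desc <- descendants(h, hit)
  if (length(desc) < min_descendants) {
    stop(errorCondition(
      sprintf("subnetwork rooted at '%s' has %d descendants (< %d required)",
              root_name, length(desc), min_descendants),
      count = length(desc),
      class = c("diseasetree_size_error", "error", "condition")))
  }
  keep <- c(hit, desc)
  sub <- hierarchy(h$nodes[h$nodes$id %in% keep, , drop = FALSE],
                   h$edges[h$edges$parent %in% keep & h$edges$child %in% keep,
                           , drop = FALSE])
  attr(sub, "root") <- hit
  sub
}
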
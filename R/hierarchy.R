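#' Disease hierarchies
#'
#' A hierarchy is a rooted directed acyclic graph (or forest) of disease
#' terms with edges pointing from parent to child. Both reference taxonomies
#' (MeSH-style trees, OBO ontologies) and inferred trees are represented this
#' way. Nodes carry an `id` and a display `name`; roots are derived as the
#' nodes without a parent.
#'
#' The constructor enforces the structural invariants: unique non-empty ids,
#' declared edge endpoints, no self-loops, no duplicate edges (silently
#' collapsed), and acyclicity.
#'
#' @param nodes a data frame with columns `id` and (optionally) `name`, or a
#'   character vector of ids (names default to ids).
#' @param edges a data frame with columns `parent` and `child` (parent-to-child
#'   direction), or `NULL` for an edgeless hierarchy.
#' @return an object of class `hierarchy`: a list with elements `nodes` and
#'   `edges`.
#' @examples
#' h <- hierarchy(c("a", "b", "c"),
#'                data.frame(parent = c("a", "b"), child = c("b", "c")))
#' roots(h)
#' ancestors(h, "c")
#' @export
hierarchy <- function(nodes, edges = NULL) {
  if (is.character(nodes)) {
    nodes <- data.frame(id = nodes, name = nodes, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(nodes), "id" %in% names(nodes))
  if (!"name" %in% names(nodes)) nodes$name <- nodes$id
  nodes <- data.frame(id = as.character(nodes$id),
                      name = as.character(nodes$name),
                      stringsAsFactors = FALSE)
  if (any(!nzchar(nodes$id)) || anyNA(nodes$id)) {
    stop("node ids must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(nodes$id)) {
    stop(sprintf("duplicate node id '%s'", nodes$id[duplicated(nodes$id)][1L]),
         call. = FALSE)
  }
  if (is.null(edges)) {
    edges <- data.frame(parent = character(), child = character(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges), all(c("parent", "child") %in% names(edges)))
  edges <- data.frame(parent = as.character(edges$parent),
                      child = as.character(edges$child),
                      stringsAsFactors = FALSE)
  undeclared <- setdiff(c(edges$parent, edges$child), nodes$id)
  if (length(undeclared)) {
    stop(sprintf("edge endpoint '%s' is not a declared node", undeclared[1L]),
         call. = FALSE)
  }
  if (any(edges$parent == edges$child)) {
    stop("self-loop edges are not allowed in a hierarchy", call. = FALSE)
  }
  edges <- unique(edges)
  rownames(edges) <- NULL
  h <- structure(list(nodes = nodes, edges = edges), class = "hierarchy")
  if (!igraph::is_dag(as_igraph(h))) {
    stop("hierarchy contains a cycle", call. = FALSE)
  }
  h
}

# igraph view of a hierarchy (internal)
as_igraph <- function(h) {
  igraph::graph_from_data_frame(h$edges, directed = TRUE,
                                vertices = h$nodes$id)
}

#' @return `roots()`: character vector of node ids with no parent.
#' @rdname hierarchy
#' @param h a `hierarchy`.
#' @export
roots <- function(h) {
  stopifnot(inherits(h, "hierarchy"))
  h$nodes$id[!(h$nodes$id %in% h$edges$child)]
}

#' Ancestors and descendants of a term
#'
#' `ancestors()` returns all proper ancestors of a node (every node from
#' which `x` is reachable through parent-to-child edges, excluding `x`
#' itself); `descendants()` the transitive children.
#'
#' @param h a [hierarchy()].
#' @param x a node id present in `h`.
#' @return a character vector of node ids (empty for a root / a leaf).
#' @export
ancestors <- function(h, x) {
  reachable_set(h, x, mode = "in")
}

#' @rdname ancestors
#' @export
descendants <- function(h, x) {
  reachable_set(h, x, mode = "out")
}

reachable_set <- function(h, x, mode) {
  stopifnot(inherits(h, "hierarchy"))
  if (length(x) != 1L || !(x %in% h$nodes$id)) {
    stop(sprintf("unknown node id '%s'", paste(x, collapse = ",")), call. = FALSE)
  }
  g <- as_igraph(h)
  ids <- names(igraph::subcomponent(g, x, mode = mode))
  setdiff(ids, x)
}

#' Proper-ancestor sets for every node
#'
#' Computes the full map node id -> character vector of proper ancestors in
#' one topological sweep. This is the workhorse behind the ancestor-based
#' evaluation metrics.
#'
#' @param h a [hierarchy()].
#' @return a named list of character vectors.
#' @export
ancestor_sets <- function(h) {
  stopifnot(inherits(h, "hierarchy"))
  g <- as_igraph(h)
  ord <- names(igraph::topo_sort(g, mode = "out"))
  parents <- split(h$edges$parent, h$edges$child)
  anc <- vector("list", length(ord))
  names(anc) <- ord
  for (v in ord) {
    ps <- parents[[v]]
    if (is.null(ps)) {
      anc[[v]] <- character()
    } else {
      anc[[v]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
    }
  }
  anc[h$nodes$id]
}

#' Topological order of a hierarchy
#'
#' @param h a [hierarchy()].
#' @return node ids ordered so that every parent precedes its children.
#' @export
topological_sort <- function(h) {
  stopifnot(inherits(h, "hierarchy"))
  names(igraph::topo_sort(as_igraph(h), mode = "out"))
}

#' @export
print.hierarchy <- function(x, ...) {
  r <- roots(x)
  cat(sprintf("Disease hierarchy: %d nodes, %d edges, %d root%s\n",
              nrow(x$nodes), nrow(x$edges), length(r),
              if (length(r) == 1L) "" else "s"))
  if (length(r) && length(r) <= 5L) {
    cat("  roots:", paste(r, collapse = ", "), "\n")
  }
  if (!is.null(attr(x, "root"))) {
    cat("  designated root:", attr(x, "root"), "\n")
  }
  invisible(x)
}

#' Write and read hierarchy edge lists
#'
#' The on-disk format is a plain edge-list TSV `parent_id<TAB>child_id` with
#' `#`-prefixed metadata lines; a designated root (for inferred trees) is
#' recorded as a `#root=<id>` header. A companion node table
#' (`id<TAB>name`) may be written alongside so that isolated nodes and
#' display names survive the round trip.
#'
#' @param h a [hierarchy()].
#' @param path edge-list file.
#' @param nodes_path optional node-table file.
#' @param comments extra `#` metadata lines (without the leading `#`).
#' @return `write_hierarchy()`: `path`, invisibly. `read_hierarchy()`: a
#'   [hierarchy()], with attribute `root` if a `#root=` header is present.
#' @export
write_hierarchy <- function(h, path, nodes_path = NULL, comments = character()) {
  stopifnot(inherits(h, "hierarchy"))
  header <- c(paste0("#", comments),
              if (!is.null(attr(h, "root"))) paste0("#root=", attr(h, "root")),
              "#parent_id\tchild_id")
  writeLines(c(header, paste(h$edges$parent, h$edges$child, sep = "\t")), path)
  if (!is.null(nodes_path)) {
    writeLines(c("#id\tname", paste(h$nodes$id, h$nodes$name, sep = "\t")),
               nodes_path)
  }
  invisible(path)
}

#' @rdname write_hierarchy
#' @export
read_hierarchy <- function(path, nodes_path = NULL) {
  edges <- read_tsv_fields(path, 2L, "hierarchy edge")
  names(edges) <- c("parent", "child")
  root <- NULL
  hdr <- grep("^#root=", readLines(path, warn = FALSE), value = TRUE)
  if (length(hdr)) root <- sub("^#root=", "", hdr[1L])
  if (!is.null(nodes_path)) {
    nodes <- read_tsv_fields(nodes_path, 2L, "hierarchy node")
    names(nodes) <- c("id", "name")
  } else {
    nodes <- data.frame(id = unique(c(edges$parent, edges$child)),
                        stringsAsFactors = FALSE)
    nodes$name <- nodes$id
  }
  h <- hierarchy(nodes, edges)
  if (!is.null(root)) attr(h, "root") <- root
  h
}
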
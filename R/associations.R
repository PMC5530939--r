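#' Disease-gene association tables
#'
#' An association table is the bipartite incidence between disease terms and
#' their associated genes. It is the single source of every similarity score
#' in the package: the gene set \eqn{G_A} of a disease and the disease set
#' \eqn{D_g} of a gene are both views of this table.
#'
#' Identifiers are opaque, case-sensitive strings (e.g. HGNC symbols for
#' genes); no normalisation or remapping is attempted. Duplicate
#' (disease, gene) pairs are collapsed on construction.
#'
#' @param pairs a data frame (or two-column matrix) whose first column holds
#'   disease identifiers and second column gene identifiers.
#' @return an object of class `association_table`: a deduplicated data frame
#'   with columns `disease_id` and `gene_id`.
#' @examples
#' tab <- association_table(data.frame(
#'   disease = c("asthma", "asthma", "copd"),
#'   gene    = c("IL13", "IL4", "IL13")))
#' disease_similarity(tab, "asthma", "copd")
#' @export
association_table <- function(pairs) {
  if (is.matrix(pairs)) pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(pairs), ncol(pairs) >= 2L)
  df <- data.frame(disease_id = as.character(pairs[[1L]]),
                   gene_id    = as.character(pairs[[2L]]),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (anyNA(df) || any(!nzchar(df$disease_id)) || any(!nzchar(df$gene_id))) {
      stop("association identifiers must be non-empty strings", call. = FALSE)
    }
    df <- unique(df)
    rownames(df) <- NULL
  }
  class(df) <- c("association_table", "data.frame")
  df
}

#' Read a disease-gene association table from a TSV file
#'
#' The file holds one `disease_id<TAB>gene_id` pair per line; lines starting
#' with `#` (e.g. a header) and blank lines are ignored. Rows with a number
#' of fields other than two raise an error naming the offending line.
#'
#' @param path path to a tab-separated file.
#' @param quiet suppress the summary message.
#' @return an [association_table()].
#' @export
read_associations <- function(path, quiet = FALSE) {
  df <- read_tsv_fields(path, 2L, "association")
  tab <- association_table(df)
  if (!quiet) {
    message(sprintf("read %d association pairs (%d diseases, %d genes) from %s",
                    nrow(tab), length(unique(tab$disease_id)),
                    length(unique(tab$gene_id)), path))
  }
  tab
}

#' Merge association tables from several sources
#'
#' Takes the set union of the records of all tables, mirroring the pooling of
#' curated databases (e.g. Mendelian plus association-study sources) into one
#' combined evidence table. Multiplicity carries no weight: a pair present in
#' two sources counts once.
#'
#' @param ... association tables, or a single list of them.
#' @return the union [association_table()].
#' @export
merge_tables <- function(...) {
  tables <- list(...)
  if (length(tables) == 1L && is.list(tables[[1L]]) &&
      !is.data.frame(tables[[1L]])) {
    tables <- tables[[1L]]
  }
  if (!length(tables)) stop("need at least one association table", call. = FALSE)
  lapply(tables, function(t) stopifnot(inherits(t, "association_table")))
  association_table(do.call(rbind, lapply(tables, as.data.frame)))
}

# gene set of one disease (internal)
gene_set <- function(table, disease) {
  table$gene_id[table$disease_id == disease]
}

# disease set of one gene (internal)
disease_set <- function(table, gene) {
  table$disease_id[table$gene_id == gene]
}

#' Jaccard similarity between two diseases
#'
#' \deqn{disease\_sim(A, B) = |G_A \cap G_B| / |G_A \cup G_B|}
#' where \eqn{G_A} is the set of genes associated with disease \eqn{A}.
#' Diseases without any associated gene cannot be scored; they are expected
#' to have been pruned from the analysis beforehand (see
#' [prune_and_reconnect()]), so an unknown disease raises an error rather
#' than scoring 0/0.
#'
#' @param table an [association_table()].
#' @param a,b disease identifiers.
#' @return a similarity in \eqn{[0, 1]}.
#' @export
disease_similarity <- function(table, a, b) {
  ga <- gene_set(table, a)
  gb <- gene_set(table, b)
  if (!length(ga)) stop(sprintf("disease '%s' has no associated genes", a),
                        call. = FALSE)
  if (!length(gb)) stop(sprintf("disease '%s' has no associated genes", b),
                        call. = FALSE)
  jaccard_index(ga, gb)
}

#' Jaccard similarity between two genes
#'
#' The mirror image of [disease_similarity()]: the Jaccard index of the sets
#' of diseases each gene is associated with.
#'
#' @inheritParams disease_similarity
#' @param g1,g2 gene identifiers.
#' @return a similarity in \eqn{[0, 1]}.
#' @export
gene_similarity <- function(table, g1, g2) {
  d1 <- disease_set(table, g1)
  d2 <- disease_set(table, g2)
  if (!length(d1)) stop(sprintf("gene '%s' not present in table", g1), call. = FALSE)
  if (!length(d2)) stop(sprintf("gene '%s' not present in table", g2), call. = FALSE)
  jaccard_index(d1, d2)
}

#' Pairwise disease similarity matrix
#'
#' Computes the full symmetric matrix of [disease_similarity()] scores via a
#' sparse incidence cross-product. The diagonal is exactly 1 for every listed
#' disease (each must have at least one gene).
#'
#' @param table an [association_table()].
#' @param diseases ordered character vector of disease ids to score; defaults
#'   to all diseases in the table, sorted.
#' @return a square numeric matrix with `diseases` as dimnames.
#' @export
build_similarity_matrix <- function(table, diseases = NULL) {
  if (is.null(diseases)) diseases <- lex_sort(unique(table$disease_id))
  diseases <- as.character(diseases)
  if (anyDuplicated(diseases)) stop("duplicated disease ids requested", call. = FALSE)
  missing <- setdiff(diseases, unique(table$disease_id))
  if (length(missing)) {
    stop(sprintf("disease '%s' has no associated genes", missing[1L]),
         call. = FALSE)
  }
  rows <- table[table$disease_id %in% diseases, , drop = FALSE]
  genes <- unique(rows$gene_id)
  inc <- Matrix::sparseMatrix(i = match(rows$gene_id, genes),
                              j = match(rows$disease_id, diseases),
                              x = 1,
                              dims = c(length(genes), length(diseases)))
  inter <- as.matrix(Matrix::crossprod(inc))
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  sim <- inter / uni
  dimnames(sim) <- list(diseases, diseases)
  sim
}

#' Convert between similarity and distance matrices
#'
#' Distances are defined by subtracting each similarity from 1, so the
#' transformation is an involution: applying it to a distance matrix returns
#' the similarities. Labels are preserved.
#'
#' @param m a square numeric matrix with values in \eqn{[0, 1]} and dimnames.
#' @return the entrywise complement `1 - m`.
#' @export
to_distance <- function(m) {
  check_square_matrix(m)
  1 - m
}

# validate a labelled symmetric [0,1] matrix (internal)
check_square_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m)) {
    stop("expected a square numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("matrix must carry disease ids as dimnames", call. = FALSE)
  }
  if (anyNA(m) || any(m < -1e-12) || any(m > 1 + 1e-12)) {
    stop("matrix entries must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(m - t(m))) > 1e-12) {
    stop("matrix must be symmetric", call. = FALSE)
  }
  invisible(m)
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("Disease-gene association table: %d pairs, %d diseases, %d genes\n",
              nrow(x), length(unique(x$disease_id)),
              length(unique(x$gene_id))))
  invisible(x)
}

#' Write an association table to TSV
#' @param table an [association_table()].
#' @param path output file.
#' @export
write_associations <- function(table, path) {
  stopifnot(inherits(table, "association_table"))
  writeLines(c("#disease_id\tgene_id",
               paste(table$disease_id, table$gene_id, sep = "\t")), path)
  invisible(path)
}
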
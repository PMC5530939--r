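# Independent brute-force oracles and random-instance generators used to
# check the package implementations. These deliberately avoid the package's
# own graph plumbing (igraph) and clustering code paths.

# random DAG on n nodes: fix topological order 1..n, give each later node
# one guaranteed random earlier parent plus extras with probability p
rand_dag <- function(n, p = 0.25, ids = sprintf("n%02d", seq_len(n))) {
  edges <- NULL
  for (j in 2:n) {
    parents <- which(stats::runif(j - 1L) < p)
    if (!length(parents)) parents <- sample.int(j - 1L, 1L)
    edges <- rbind(edges, data.frame(parent = ids[parents], child = ids[j],
                                     stringsAsFactors = FALSE))
  }
  hierarchy(ids, edges)
}

# boolean transitive closure by iterated matrix multiplication;
# result[a, x] is TRUE iff a is a proper ancestor of x
oracle_closure <- function(h) {
  ids <- h$nodes$id
  n <- length(ids)
  M <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (nrow(h$edges)) M[cbind(h$edges$parent, h$edges$child)] <- TRUE
  R <- M
  repeat {
    R2 <- R | ((R %*% M) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

oracle_ancestors <- function(closure, x) rownames(closure)[closure[, x]]

# all five metrics recomputed from closure matrices, straight from their
# definitions
oracle_eval <- function(ref, inf) {
  cr <- oracle_closure(ref)
  ci <- oracle_closure(inf)
  key <- function(e) paste(e$parent, e$child)
  ec <- mean(key(ref$edges) %in% key(inf$edges))
  shared <- intersect(ref$nodes$id, inf$nodes$id)
  aj <- hp <- hr <- rep(NA_real_, length(shared))
  for (k in seq_along(shared)) {
    x <- shared[k]
    a_ref <- oracle_ancestors(cr, x)
    a_inf <- oracle_ancestors(ci, x)
    common <- length(intersect(a_ref, a_inf))
    if (length(a_ref) + length(a_inf) > 0) {
      aj[k] <- common / length(union(a_ref, a_inf))
    }
    if (length(a_inf) > 0) hp[k] <- common / length(a_inf)
    if (length(a_ref) > 0) hr[k] <- common / length(a_ref)
  }
  ap <- mean(hp[!is.na(hp)])
  ar <- mean(hr[!is.na(hr)])
  list(ec = ec, ac = mean(aj[!is.na(aj)]), ap = ap, ar = ar,
       f = if (ap + ar == 0) 0 else 2 * ap * ar / (ap + ar))
}

# naive O(n^3) complete-linkage agglomeration, recomputing every
# cluster-pair distance from the original matrix at each step
oracle_complete_linkage_heights <- function(d) {
  clusters <- as.list(rownames(d))
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- Inf
    bi <- bj <- 0L
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          dij <- max(d[clusters[[i]], clusters[[j]]])
          if (dij < best) { best <- dij; bi <- i; bj <- j }
        }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# exact minimum spanning-tree weight by enumerating all n^(n-2) labelled
# trees through Prufer sequences
oracle_mst_weight <- function(d) {
  n <- nrow(d)
  if (n == 2L) return(d[1L, 2L])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    s <- seqs[r, ]
    degree <- rep(1L, n)
    for (v in s) degree[v] <- degree[v] + 1L
    w <- 0
    for (v in s) {
      leaf <- which(degree == 1L)[1L]
      w <- w + d[leaf, v]
      degree[leaf] <- 0L
      degree[v] <- degree[v] - 1L
    }
    ends <- which(degree == 1L)
    w <- w + d[ends[1L], ends[2L]]
    if (w < best) best <- w
  }
  best
}

# random labelled symmetric distance matrix with distinct off-diagonal
# entries and zero diagonal
rand_dist <- function(n, ids = sprintf("t%02d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  vals <- sample(seq(0.01, 0.99, length.out = n * (n - 1L) / 2L))
  m[upper.tri(m)] <- vals
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Kahn's algorithm, independent of the package's topological_sort
oracle_topo <- function(h) {
  ids <- h$nodes$id
  indeg <- stats::setNames(integer(length(ids)), ids)
  tab <- table(h$edges$child)
  indeg[names(tab)] <- as.integer(tab)
  remaining <- h$edges
  avail <- ids[indeg == 0L]
  out <- character()
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    out <- c(out, v)
    ch <- remaining$child[remaining$parent == v]
    remaining <- remaining[remaining$parent != v, , drop = FALSE]
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- c(avail, w)
    }
  }
  out
}

# a chain hierarchy following a given node order
chain_hierarchy <- function(ord) {
  hierarchy(ord, data.frame(parent = ord[-length(ord)], child = ord[-1L],
                            stringsAsFactors = FALSE))
}

# six-term worked dendrogram: {5,6} merge first (6 more cited than 5),
# {1,2} then {1,2,4} form on the other side, 3 joins {5,6} and wins every
# later contest because it has the most citations
worked_promotion_fixture <- function() {
  labs <- as.character(1:6)
  d <- matrix(0.9, 6L, 6L, dimnames = list(labs, labs))
  diag(d) <- 0
  d["5", "6"] <- d["6", "5"] <- 0.1
  d["1", "2"] <- d["2", "1"] <- 0.2
  d["1", "4"] <- d["4", "1"] <- 0.3
  d["2", "4"] <- d["4", "2"] <- 0.3
  d["3", "5"] <- d["5", "3"] <- 0.4
  d["3", "6"] <- d["6", "3"] <- 0.4
  citations <- c("1" = 50, "2" = 5, "3" = 100, "4" = 3, "5" = 10, "6" = 40)
  list(d = d, citations = citations)
}

edge_keys <- function(h) sort(paste(h$edges$parent, h$edges$child, sep = ">"))
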
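test_that("complete linkage merges by maximum pairwise distance", {
  two <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                         c("a", "b")))
  hc <- complete_linkage(two)
  expect_equal(hc$height, 0.4)

  labs <- c("p1", "p2", "p3")
  d <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, 3, dimnames = list(labs, labs))
  hc <- complete_linkage(d)
  expect_equal(hc$height, c(0.1, 0.9))
  expect_equal(sort(labs[-hc$merge[1, ]]), c("p1", "p2"))

  one <- matrix(0, 1, 1, dimnames = list("x", "x"))
  expect_error(complete_linkage(one), "at least two")
})

test_that("complete-linkage heights match a naive agglomeration oracle", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    d <- rand_dist(n)
    hc <- complete_linkage(d)
    expect_equal(hc$height, oracle_complete_linkage_heights(d),
                 tolerance = 1e-12)
    expect_true(all(diff(hc$height) >= 0))   # monotone merge heights
  }
})

test_that("parent promotion reproduces the worked six-term ordering", {
  fx <- worked_promotion_fixture()
  tree <- parent_promotion(complete_linkage(fx$d), fx$citations)
  # 6 beats 5 in the first merge, 3 then beats 6 and every later contender,
  # while 5 stays under 6
  expect_equal(edge_keys(tree),
               sort(c("6>5", "3>6", "1>2", "1>4", "3>1")))
  expect_equal(attr(tree, "root"), "3")
  expect_equal(roots(tree), "3")
})

test_that("parent promotion handles two leaves and citation ties", {
  d <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("b", "a"),
                                                       c("b", "a")))
  tree <- parent_promotion(complete_linkage(d), c(a = 10, b = 3))
  expect_equal(edge_keys(tree), "a>b")

  # equal citations: the lexicographically smaller id becomes the parent
  tied <- parent_promotion(complete_linkage(d), c(a = 5, b = 5))
  expect_equal(edge_keys(tied), "a>b")
  expect_equal(attr(tied, "root"), "a")

  expect_error(parent_promotion(complete_linkage(d), c(a = 1)),
               "missing citation count for disease 'b'")
})

test_that("parent promotion output is a rooted tree ordered by citations", {
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    d <- rand_dist(n)
    citations <- stats::setNames(sample(1000, n), rownames(d))
    tree <- parent_promotion(complete_linkage(d), citations)
    expect_equal(nrow(tree$edges), n - 1L)
    expect_length(roots(tree), 1L)
    expect_true(all(citations[tree$edges$parent] >=
                      citations[tree$edges$child]))
  }
})

test_that("the spanning tree picks the highest-similarity backbone", {
  # s(A,B)=0.9, s(B,C)=0.8, s(A,C)=0.1: of the three spanning trees the
  # minimum-distance one is {A-B, B-C}; C is the most cited, so edges point
  # C -> B -> A
  labs <- c("A", "B", "C")
  sim <- matrix(c(1, 0.9, 0.1,
                  0.9, 1, 0.8,
                  0.1, 0.8, 1), 3, 3, dimnames = list(labs, labs))
  tree <- mwst_infer(to_distance(sim), c(A = 5, B = 10, C = 50))
  expect_equal(edge_keys(tree), sort(c("C>B", "B>A")))
  expect_equal(attr(tree, "root"), "C")

  two <- matrix(c(0, 0.3, 0.3, 0), 2, 2, dimnames = list(c("u", "v"),
                                                         c("u", "v")))
  t2 <- mwst_infer(two, c(u = 1, v = 9))
  expect_equal(edge_keys(t2), "v>u")
})

test_that("spanning-tree weight matches exhaustive enumeration", {
  set.seed(61)
  for (rep in 1:15) {
    n <- sample(3:6, 1)
    d <- rand_dist(n)
    citations <- stats::setNames(sample(1000, n), rownames(d))
    tree <- mwst_infer(d, citations)
    expect_equal(attr(tree, "total_weight"), oracle_mst_weight(d),
                 tolerance = 1e-12)
    # cross-check against an independent MST implementation
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(attr(tree, "total_weight"),
                 sum(igraph::E(igraph::mst(g))$weight), tolerance = 1e-12)
  }
})

test_that("infer composes similarity, distance, and method deterministically", {
  set.seed(71)
  fx <- make_separable_fixture(12, seed = 5)
  diseases <- sort(fx$taxonomy$nodes$id)

  manual <- parent_promotion(
    complete_linkage(to_distance(
      build_similarity_matrix(fx$associations, diseases))),
    fx$citations)
  composed <- infer("parent_promotion", fx$associations, diseases,
                    fx$citations, quiet = TRUE)
  expect_equal(edge_keys(composed), edge_keys(manual))

  again <- infer("pp", fx$associations, diseases, fx$citations, quiet = TRUE)
  expect_equal(edge_keys(again), edge_keys(composed))
  expect_equal(attr(again, "root"), attr(composed, "root"))

  m1 <- infer("mwst", fx$associations, diseases, fx$citations, quiet = TRUE)
  m2 <- infer("mwst", fx$associations, diseases, fx$citations, quiet = TRUE)
  expect_equal(edge_keys(m1), edge_keys(m2))
})

test_that("inference is invariant to the labelling order of the input", {
  set.seed(81)
  n <- 9
  d <- rand_dist(n)
  citations <- stats::setNames(sample(1000, n), rownames(d))
  perm <- sample(rownames(d))
  dp <- d[perm, perm]

  pp1 <- parent_promotion(complete_linkage(d), citations)
  pp2 <- parent_promotion(complete_linkage(dp), citations)
  expect_equal(edge_keys(pp1), edge_keys(pp2))

  mw1 <- mwst_infer(d, citations)
  mw2 <- mwst_infer(dp, citations)
  expect_equal(edge_keys(mw1), edge_keys(mw2))
})
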
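obo_file <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(lines, path)
  path
}

test_that("OBO parsing inverts is_a, skips obsolete terms, keeps synonyms", {
  path <- obo_file(c(
    "format-version: 1.2", "",
    "[Term]", "id: DOID:a", "name: disease",
    "synonym: \"illness\" EXACT []", "",
    "[Term]", "id: DOID:b", "name: heart disease", "is_a: DOID:a ! disease", "",
    "[Term]", "id: DOID:c", "name: arrhythmia", "is_a: DOID:b", "",
    "[Term]", "id: DOID:z", "name: retired", "is_obsolete: true", "",
    "[Typedef]", "id: part_of"))
  h <- read_obo(path)
  expect_setequal(h$nodes$id, c("DOID:a", "DOID:b", "DOID:c"))
  expect_equal(edge_keys(h), sort(c("DOID:a>DOID:b", "DOID:b>DOID:c")))
  expect_equal(roots(h), "DOID:a")
  expect_equal(attr(h, "synonyms")[["DOID:a"]], "illness")

  # a term with two is_a parents has in-degree 2
  path2 <- obo_file(c(
    "[Term]", "id: a", "name: a", "",
    "[Term]", "id: b", "name: b", "",
    "[Term]", "id: c", "name: c", "is_a: a", "is_a: b"))
  h2 <- read_obo(path2)
  expect_equal(sum(h2$edges$child == "c"), 2L)
})

test_that("OBO structural errors are reported", {
  expect_error(read_obo(obo_file(c("[Term]", "id: a", "name: a",
                                   "is_a: ghost"))),
               "undeclared")
  expect_error(read_obo(obo_file(c(
    "[Term]", "id: a", "name: a", "is_a: b", "",
    "[Term]", "id: b", "name: b", "is_a: a"))),
    "cycle")
})

test_that("MeSH tree numbers build a DAG with repeated names merged", {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))

  writeLines(c("A\tC01", "B\tC01.1", "C\tC01.2"), path)
  star <- read_mesh_trees(path)
  expect_equal(edge_keys(star), sort(c("A>B", "A>C")))
  expect_equal(roots(star), "A")

  # the same name at two positions becomes one node with two parents
  writeLines(c("A\tC01", "D\tC02", "X\tC01.1", "X\tC02.5"), path)
  merged <- read_mesh_trees(path)
  expect_equal(nrow(merged$nodes), 3L)
  expect_setequal(merged$edges$parent[merged$edges$child == "X"], c("A", "D"))

  # merging a name that is its own ancestor elsewhere drops the self-loop
  writeLines(c("A\tC01", "X\tC01.1", "X\tC01.1.9"), path)
  expect_warning(looped <- read_mesh_trees(path), "self-loop")
  expect_equal(edge_keys(looped), "A>X")

  writeLines(c("A\tC01", "B\tC01..2"), path)
  expect_error(read_mesh_trees(path), "malformed tree number")
})

test_that("pruning deletes geneless terms and reconnects nearest ancestors", {
  tab <- association_table(data.frame(d = c("r", "y"), g = c("g1", "g2")))
  chain <- hierarchy(c("r", "x", "y"),
                     data.frame(parent = c("r", "x"), child = c("x", "y")))
  pruned <- suppressMessages(prune_and_reconnect(chain, tab))
  expect_setequal(pruned$nodes$id, c("r", "y"))
  expect_equal(edge_keys(pruned), "r>y")

  # geneless root: its gene-bearing children become a two-root forest
  fork <- hierarchy(c("root", "a", "b"),
                    data.frame(parent = c("root", "root"), child = c("a", "b")))
  tab2 <- association_table(data.frame(d = c("a", "b"), g = c("g1", "g2")))
  forest <- suppressMessages(prune_and_reconnect(fork, tab2))
  expect_setequal(roots(forest), c("a", "b"))
  expect_equal(nrow(forest$edges), 0L)
})

test_that("pruning preserves retained-pair reachability and is idempotent", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    h <- rand_dag(n, p = 0.3)
    keep <- sample(h$nodes$id, sample(2:(n - 1), 1))
    tab <- association_table(data.frame(d = keep, g = paste0("g_", keep)))
    pruned <- suppressMessages(prune_and_reconnect(h, tab))
    expect_setequal(pruned$nodes$id, keep)

    closure_full <- oracle_closure(h)
    closure_pruned <- oracle_closure(pruned)
    expect_equal(closure_pruned[keep, keep, drop = FALSE],
                 closure_full[keep, keep, drop = FALSE])

    again <- suppressMessages(prune_and_reconnect(pruned, tab))
    expect_setequal(again$nodes$id, pruned$nodes$id)
    expect_equal(edge_keys(again), edge_keys(pruned))
  }
})

test_that("subnetwork extraction returns the induced rooted sub-DAG", {
  # root -> mid (120 descendants via a broad subtree) and a stray leaf
  mid_children <- sprintf("m%03d", 1:120)
  nodes <- c("top", "mid", "leaf", mid_children)
  edges <- rbind(
    data.frame(parent = "top", child = c("mid", "leaf")),
    data.frame(parent = "mid", child = mid_children))
  h <- hierarchy(nodes, edges)

  sub <- extract_subnetwork(h, "mid", min_descendants = 100)
  expect_equal(nrow(sub$nodes), 121L)
  expect_equal(roots(sub), "mid")
  expect_true(all(sub$nodes$id %in% c("mid", descendants(h, "mid"))))

  whole <- extract_subnetwork(h, "top", min_descendants = 1)
  expect_equal(nrow(whole$nodes), nrow(h$nodes))

  err <- tryCatch(extract_subnetwork(h, "leaf", min_descendants = 100),
                  diseasetree_size_error = function(e) e)
  expect_s3_class(err, "diseasetree_size_error")
  expect_equal(err$count, 0L)
  expect_error(extract_subnetwork(h, "ghost"), "no node named")
})

test_that("ancestor queries walk the transitive parent closure", {
  chain <- hierarchy(c("a", "b", "c"),
                     data.frame(parent = c("a", "b"), child = c("b", "c")))
  expect_equal(ancestors(chain, "a"), character())
  expect_setequal(ancestors(chain, "c"), c("a", "b"))

  diamond <- hierarchy(c("a", "b", "c", "d"),
                       data.frame(parent = c("a", "a", "b", "c"),
                                  child = c("b", "c", "d", "d")))
  expect_setequal(ancestors(diamond, "d"), c("a", "b", "c"))
  expect_setequal(descendants(diamond, "a"), c("b", "c", "d"))
  expect_error(ancestors(diamond, "nope"), "unknown node")
})

test_that("hierarchy edge lists survive a round trip through TSV", {
  h <- rand_dag(8)
  attr(h, "root") <- roots(h)[1]
  edges_path <- tempfile()
  nodes_path <- tempfile()
  write_hierarchy(h, edges_path, nodes_path, comments = "fixture")
  back <- read_hierarchy(edges_path, nodes_path)
  expect_equal(edge_keys(back), edge_keys(h))
  expect_setequal(back$nodes$id, h$nodes$id)
  expect_equal(attr(back, "root"), attr(h, "root"))
})
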
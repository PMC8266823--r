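test_that("edge-list reader keeps type-distinct duplicates and validates rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\ttype\tweight",
               "a\tb\tdirected\t1.0",
               "a\tb\tundirected\t1.0"), f)
  net <- read_edge_list(f)
  expect_equal(length(net$nodes), 2L)
  expect_equal(nrow(net$edges), 2L)  # distinct by directedness
  expect_setequal(net$edges$directed, c(TRUE, FALSE))

  writeLines(c("source\ttarget\ttype\tweight", "a\ta\tdirected\t1.0"), f)
  expect_warning(net2 <- read_edge_list(f), "self-loop")
  expect_equal(net2$nodes, "a")
  expect_equal(nrow(net2$edges), 0L)

  writeLines(c("source\ttarget\ttype\tweight", "a\tb\tdirected\t1.5"), f)
  expect_error(read_edge_list(f), "line 2.*1\\.5")

  writeLines(c("source\ttarget\ttype\tweight", "a\tb\tsideways\t1.0"), f)
  expect_error(read_edge_list(f), "line 2.*sideways")

  writeLines(c("source\ttarget\ttype\tweight", "a\tb"), f)
  expect_error(read_edge_list(f), "line 2")
})

test_that("edge-list round-trip reproduces the normalized edge set", {
  for (seed in c(11, 12, 13)) {
    net <- random_network(8, seed, weighted = TRUE)
    if (nrow(net$edges) == 0L) next
    f <- withr::local_tempfile(fileext = ".tsv")
    write_edge_list(net, f)
    back <- read_edge_list(f)
    expect_equal(back$edges[c("source", "target", "directed", "weight")],
                 net$edges[c("source", "target", "directed", "weight")])
  }
})

test_that("duplicate edges collapse to the maximum weight", {
  net <- signaling_network(c("a", "b"), data.frame(
    source = c("a", "a", "b"), target = c("b", "b", "a"),
    directed = c(TRUE, TRUE, FALSE), weight = c(0.3, 0.8, 0.5)))
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$edges$weight[net$edges$directed], 0.8)
  # undirected duplicates match unordered
  net2 <- signaling_network(c("a", "b"), data.frame(
    source = c("a", "b"), target = c("b", "a"),
    directed = FALSE, weight = c(0.4, 0.9)))
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$weight, 0.9)
})

test_that("constructor enforces node and weight invariants", {
  expect_error(signaling_network(character()), "at least one node")
  expect_error(signaling_network(c("a", "a")), "duplicate")
  expect_error(signaling_network("a", data.frame(
    source = "a", target = "zz", directed = TRUE)), "zz")
  expect_error(signaling_network(c("a", "b"), data.frame(
    source = "a", target = "b", directed = TRUE, weight = 0)), "\\(0, 1\\]")
})

test_that("KGML reader maps entries and relation subtypes", {
  f <- make_kgml_fixture(list(
    entries = list(list(id = "1", name = "hsa:1", graphics = "GA"),
                   list(id = "2", name = "hsa:2", graphics = "GB"),
                   list(id = "3", name = "hsa:3", graphics = "GC")),
    relations = list(list(entry1 = "1", entry2 = "2",
                          subtype = "activation"))))
  net <- read_kgml(f)
  expect_setequal(net$nodes, c("GA", "GB", "GC"))
  expect_equal(nrow(net$edges), 1L)
  expect_true(net$edges$directed)
  expect_equal(net$edges[1, c("source", "target")],
               data.frame(source = "GA", target = "GB"),
               ignore_attr = TRUE)

  f2 <- make_kgml_fixture(list(
    entries = list(list(id = "1", name = "hsa:1", graphics = "GA"),
                   list(id = "2", name = "hsa:2", graphics = "GB")),
    relations = list(list(entry1 = "1", entry2 = "2",
                          subtype = "binding/association"))))
  net2 <- read_kgml(f2)
  expect_false(net2$edges$directed)

  f3 <- make_kgml_fixture(list(
    entries = list(list(id = "1", name = "hsa:1", graphics = "GA"),
                   list(id = "2", name = "hsa:2", graphics = "GB")),
    relations = list(list(entry1 = "1", entry2 = "2",
                          subtype = "glycosylation"))))
  expect_warning(net3 <- read_kgml(f3), "glycosylation")
  expect_true(net3$edges$directed)
  expect_equal(net3$edges$subtype, "glycosylation")
})

test_that("KGML reader expands groups and paralogous entries", {
  f <- make_kgml_fixture(list(
    entries = list(list(id = "1", name = "hsa:1", graphics = "A"),
                   list(id = "2", name = "hsa:2", graphics = "B1"),
                   list(id = "3", name = "hsa:3", graphics = "B2")),
    groups = list(list(id = "9", components = c("2", "3"))),
    relations = list(list(entry1 = "1", entry2 = "9",
                          subtype = "activation"))))
  net <- read_kgml(f)
  expect_setequal(net$nodes, c("A", "B1", "B2"))
  dir_e <- net$edges[net$edges$directed, ]
  expect_setequal(dir_e$target, c("B1", "B2"))
  expect_true(all(dir_e$source == "A"))
  und_e <- net$edges[!net$edges$directed, ]
  expect_equal(nrow(und_e), 1L)  # B1 -- B2 complex link

  # paralogous entry: one node per gene id, no intra-entry edges
  f2 <- make_kgml_fixture(list(
    entries = list(list(id = "1", name = "hsa:1", graphics = "A"),
                   list(id = "2", name = "hsa:2 hsa:3",
                        graphics = "P1, P2, ...")),
    relations = list(list(entry1 = "1", entry2 = "2",
                          subtype = "expression"))))
  net2 <- read_kgml(f2)
  expect_setequal(net2$nodes, c("A", "P1", "P2"))
  expect_equal(nrow(net2$edges), 2L)
  expect_true(all(net2$edges$directed))
})

test_that("KGML reader rejects malformed input and unknown references", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<pathway name='x' <entry", bad)
  expect_error(read_kgml(bad))

  dangling <- withr::local_tempfile(fileext = ".xml")
  writeLines(c('<pathway name="p" title="t">',
               '<entry id="1" name="hsa:1" type="gene">',
               '<graphics name="GA"/></entry>',
               '<relation entry1="1" entry2="99" type="PPrel">',
               '<subtype name="activation" value=""/></relation>',
               '</pathway>'), dangling)
  expect_error(read_kgml(dangling), "99")
})

test_that("group expansion replicates edges and completes member cliques", {
  net <- signaling_network(c("A", "B1", "B2", "grp"), data.frame(
    source = "A", target = "grp", directed = TRUE))
  ex <- expand_group_nodes(net, list(grp = c("B1", "B2")))
  expect_false("grp" %in% ex$nodes)
  dir_e <- ex$edges[ex$edges$directed, ]
  expect_setequal(paste(dir_e$source, dir_e$target),
                  c("A B1", "A B2"))
  expect_equal(sum(!ex$edges$directed), 1L)

  # three members, no external edges: a triangle
  net3 <- signaling_network(c("m1", "m2", "m3", "g"))
  ex3 <- expand_group_nodes(net3, list(g = c("m1", "m2", "m3")))
  expect_equal(nrow(ex3$edges), 3L)
  expect_true(all(!ex3$edges$directed))

  # pre-existing member edge is not duplicated
  net4 <- signaling_network(c("m1", "m2", "g"), data.frame(
    source = "m1", target = "m2", directed = FALSE))
  ex4 <- expand_group_nodes(net4, list(g = c("m1", "m2")))
  expect_equal(nrow(ex4$edges), 1L)

  expect_error(expand_group_nodes(net4, list(g = c("m1", "nope"))), "nope")
})

test_that("group expansion arithmetic: clique edges added, group nodes removed", {
  net <- signaling_network(c(sprintf("x%d", 1:6), "g1", "g2"), data.frame(
    source = c("x1", "g1"), target = c("g1", "x5"),
    directed = c(TRUE, TRUE)))
  groups <- list(g1 = c("x2", "x3", "x4"), g2 = c("x5", "x6"))
  ex <- expand_group_nodes(net, groups)
  expect_equal(length(ex$nodes), 6L)
  k <- c(3, 2)
  expect_equal(sum(!ex$edges$directed), sum(k * (k - 1) / 2))
  # replicated group edges: x1 -> each of g1's 3 members, each member -> x5
  expect_equal(sum(ex$edges$directed), 3L + 3L)
})

test_that("influence matrix follows the receiver-row convention", {
  net <- signaling_network(c("a", "b"), data.frame(
    source = "a", target = "b", directed = TRUE))
  m <- to_influence_matrix(net)
  expect_equal(m$S["b", "a"], 1)
  expect_equal(m$S["a", "b"], 0)
  expect_equal(unname(m$D[c("a", "b")]), c(0, 1))

  net2 <- signaling_network(c("a", "b"), data.frame(
    source = "a", target = "b", directed = FALSE, weight = 0.5))
  m2 <- to_influence_matrix(net2)
  expect_equal(m2$S["a", "b"], 0.5)
  expect_equal(m2$S["b", "a"], 0.5)

  leaves <- c("p", "q", "r")
  star <- signaling_network(c("c", leaves), data.frame(
    source = leaves, target = "c", directed = TRUE))
  m3 <- to_influence_matrix(star)
  expect_equal(m3$W_max, 3)
  expect_equal(unname(m3$D["c"]), 3)
})

test_that("directed and undirected edges on one pair add in the matrix", {
  net <- signaling_network(c("a", "b"), data.frame(
    source = c("a", "a"), target = c("b", "b"),
    directed = c(TRUE, FALSE), weight = c(0.7, 0.4)))
  m <- to_influence_matrix(net)
  expect_equal(m$S["b", "a"], 1.1)
  expect_equal(m$S["a", "b"], 0.4)
})

test_that("row sums match an independent recount over the edge list", {
  for (seed in 21:26) {
    net <- random_network(9, seed, weighted = TRUE)
    m <- to_influence_matrix(net)
    expect_true(all(diag(m$S) == 0))
    recount <- vapply(net$nodes, function(u) {
      e <- net$edges
      sum(e$weight[e$directed & e$target == u]) +
        sum(e$weight[!e$directed & (e$source == u | e$target == u)])
    }, numeric(1))
    expect_equal(m$D, recount)
    expect_equal(m$W_max, max(recount))
  }
})
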
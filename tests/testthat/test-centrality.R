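test_that("local_vital_nodes applies the strict mean-degree threshold", {
  expect_identical(local_vital_nodes(g_star(4)), "c0")
  expect_identical(local_vital_nodes(g_cycle(8)), character(0))
  g <- ba_graph(100, 2, seed = 3)
  deg <- igraph::degree(g)
  brute <- names(deg)[deg > mean(deg)]
  expect_setequal(local_vital_nodes(g), brute)
  # ordering: degree descending, then label
  lv <- local_vital_nodes(g)
  d <- deg[lv]
  expect_true(all(diff(d) <= 0))
})

test_that("enumerate_valid_paths finds exactly the bounded simple paths", {
  ps <- enumerate_valid_paths(g_triangle(), "a", "b")
  expect_equal(ps$k, 2)
  expect_identical(ps$paths, list(c("a", "b"), c("a", "c", "b")))

  long <- g_path(8) # 7 edges end to end
  ends <- range(igraph::V(long)$name)
  expect_equal(enumerate_valid_paths(long, ends[1], ends[2], l_max = 6)$k, 0)
  expect_equal(enumerate_valid_paths(long, ends[1], ends[2], l_max = 7)$k, 1)

  expect_error(enumerate_valid_paths(g_triangle(), "a", "a"), "distinct")
  expect_error(enumerate_valid_paths(g_triangle(), "a", "b", l_max = 0), "l_max")
})

test_that("enumerate_valid_paths matches the exhaustive oracle on random graphs", {
  for (s in 1:20) {
    g <- g_random(sample(5:12, 1), runif(1, 0.2, 0.5), seed = 500 + s)
    lab <- igraph::V(g)$name
    pair <- sample(lab, 2)
    lmax <- sample(2:6, 1)
    got <- enumerate_valid_paths(g, pair[1], pair[2], l_max = lmax)
    want <- oracle_paths(g, pair[1], pair[2], lmax)
    expect_identical(path_key(got$paths), path_key(want))
    # lexicographic emission order (tab separator sorts below any label
    # character, so joined-string order equals node-sequence order)
    joined <- vapply(got$paths, paste, character(1), collapse = "\t")
    expect_identical(joined, sort(joined, method = "radix"))
  }
})

test_that("path_diversity matches hand-computed pair overlaps", {
  expect_equal(path_diversity(list(c("a", "x", "b"), c("a", "y", "b"))), 1)
  expect_equal(path_diversity(list(c("a", "x", "y", "b"),
                                   c("a", "x", "z", "b"))), 0.5)
  expect_equal(path_diversity(list(c("a", "x", "b"))), 0)
  expect_equal(path_diversity(list()), 0)
  # direct edge paired with a longer path shares no interior: contributes 1
  expect_equal(path_diversity(list(c("a", "b"), c("a", "x", "b"))), 1)
  # three paths, mixed overlap, against the independent oracle
  paths <- list(c("a", "x", "b"), c("a", "x", "y", "b"), c("a", "z", "b"))
  expect_equal(path_diversity(paths), oracle_pd(paths))
})

test_that("node_reachability follows the averaging and no-path conventions", {
  cyc4 <- g_edges(c("a", "b", "c", "d"), c("b", "c", "d", "a"))
  r <- node_reachability(cyc4, vital = c("a", "c"), node = "a")
  expect_equal(r$pd, 1)
  expect_equal(r$pn, 2)
  expect_equal(r$pl, 2)

  # vital pair in different components: worst-case conventions
  two <- g_edges(c("a", "b", "x", "y"), c("b", "c", "y", "z"))
  r2 <- node_reachability(two, vital = c("b", "y"), node = "b", l_max = 6)
  expect_equal(r2$pd, 0)
  expect_equal(r2$pn, 0)
  expect_equal(r2$pl, 7)

  expect_error(node_reachability(cyc4, c("a", "c"), "b"), "vital")
})

test_that("minmax_norm maps to [0,1] with the all-equal convention", {
  expect_equal(minmax_norm(c(1, 3, 5)), c(0, 0.5, 1))
  expect_equal(minmax_norm(c(2, 2, 2)), c(0.5, 0.5, 0.5))
  expect_error(minmax_norm(c(1, NaN)), "finite")
  expect_error(minmax_norm(numeric(0)), "non-empty")
  for (s in 1:10) {
    x <- rnorm(sample(2:20, 1))
    y <- minmax_norm(x)
    expect_true(all(y >= 0 & y <= 1))
    expect_identical(order(x), order(y))
  }
})

test_that("spread_centrality matches a straight-from-equations recomputation", {
  # the two independent oracle routes (pure-R recursion; igraph paths)
  # agree with each other on a small instance
  g0 <- ba_graph(16, 2, seed = 2)
  o1 <- oracle_spread_centrality(g0)
  o2 <- oracle_spread_centrality_ig(g0)
  expect_equal(o1, o2, tolerance = 1e-12)

  for (seed in c(11, 23, 47)) {
    g <- ba_graph(30, 2, seed = seed)
    got <- spread_centrality(g)
    want <- oracle_spread_centrality_ig(g)
    gv <- got[got$vital, ]
    expect_setequal(gv$node, want$node)
    m <- match(want$node, gv$node)
    expect_equal(gv$pd[m], want$pd, tolerance = 1e-12)
    expect_equal(gv$pn[m], want$pn, tolerance = 1e-12)
    expect_equal(gv$pl[m], want$pl, tolerance = 1e-12)
    expect_equal(gv$sc[m], want$sc, tolerance = 1e-12)
  }
})

test_that("spread_centrality respects symmetry, bounds and the vital rule", {
  # complete bipartite K2,6: the two hubs are interchangeable
  k26 <- g_edges(rep(c("h1", "h2"), each = 6), rep(paste0("m", 1:6), 2))
  sc <- spread_centrality(k26)
  expect_setequal(sc$node[sc$vital], c("h1", "h2"))
  expect_equal(sc$sc[sc$vital], c(0.5, 0.5))
  expect_true(all(sc$sc[!sc$vital] == 0))

  g <- ba_graph(60, 2, seed = 11)
  sc <- spread_centrality(g)
  expect_true(all(sc$sc >= 0 & sc$sc <= 1))
  v <- sc$sc[sc$vital]
  expect_gte(max(v), mean(v))

  expect_error(spread_centrality(g_cycle(10)),
               class = "spreadrank_too_few_vital")
})

test_that("spread_centrality is invariant under node relabeling", {
  g <- ba_graph(40, 2, seed = 19)
  lab <- igraph::V(g)$name
  set.seed(99)
  newlab <- paste0("z", sample(seq_along(lab)))
  g2 <- g
  igraph::V(g2)$name <- newlab
  sc1 <- spread_centrality(g)
  sc2 <- spread_centrality(as_spread_network(g2))
  m <- match(newlab[match(sc1$node, lab)], sc2$node)
  expect_equal(sc2$sc[m], sc1$sc, tolerance = 1e-12)
  expect_equal(sc2$pd[m], sc1$pd, tolerance = 1e-12)
})

test_that("adding a disjoint parallel path never decreases PD or PN", {
  base <- g_edges(c("a", "x", "a", "y"), c("x", "b", "y", "b"))
  ps1 <- enumerate_valid_paths(base, "a", "b")
  more <- g_edges(c("a", "x", "a", "y", "a", "z"),
                  c("x", "b", "y", "b", "z", "b"))
  ps2 <- enumerate_valid_paths(more, "a", "b")
  expect_gte(ps2$k, ps1$k)
  expect_gte(path_diversity(ps2), path_diversity(ps1) - 1e-12)
})
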
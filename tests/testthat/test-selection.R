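test_that("attenuation halves neighbours, quarters second-order, compounds", {
  g <- g_path(5) # p001 - p002 - p003 - p004 - p005
  w <- setNames(rep(0.8, 5), sprintf("p%03d", 1:5))
  w1 <- attenuate_scores(w, g, "p001")
  expect_equal(unname(w1["p001"]), 0)
  expect_equal(unname(w1["p002"]), 0.4)   # distance 1: retain 1/2
  expect_equal(unname(w1["p003"]), 0.6)   # distance 2: retain 3/4
  expect_equal(unname(w1["p004"]), 0.8)   # distance >= 3: unchanged
  expect_equal(unname(w1["p005"]), 0.8)

  # a node adjacent to two successive picks loses 1/2 twice
  tri <- g_triangle()
  w <- setNames(c(0.8, 0.8, 0.8), c("a", "b", "c"))
  w <- attenuate_scores(w, tri, "a")
  w <- attenuate_scores(w, tri, "b", selected = "a")
  expect_equal(unname(w["c"]), 0.8 * 0.5 * 0.5)

  expect_error(attenuate_scores(w, tri, "a", selected = c("a", "b")),
               "already selected")
})

test_that("addition stage stops at the giant-component threshold", {
  # star: the hub alone shatters the graph (via the degree fallback,
  # since a star has a single vital node)
  st <- g_star(8)
  s <- spreadrank_select(st, mu = 0.5)
  expect_identical(s$selected, "c0")
  expect_equal(s$q, 1 / 9)

  # threshold so loose that any single removal satisfies it
  g <- ba_graph(20, 2, seed = 4)
  sc <- spread_centrality(g)
  pre <- addition_stage(g, sc, mu = 0.99)
  expect_length(pre, 1)

  expect_error(addition_stage(g, sc, mu = 1.5), "mu")
})

test_that("addition stage postconditions replay on a BA instance", {
  g <- ba_graph(200, 2, seed = 5)
  sc <- spread_centrality(g)
  pre <- addition_stage(g, sc, mu = 0.05)
  S <- as.character(pre)
  expect_lt(gcc_fraction(g, S), 0.05)
  expect_gte(gcc_fraction(g, S[-length(S)]), 0.05)
})

test_that("deletion stage prunes redundant picks and replays", {
  # 10-node fixture: hub h cut vertex; leaf node 'r' in the preselected set
  # is redundant (its removal never affected connectivity)
  fix <- g_edges(c("h", "h", "h", "h", "a", "a", "b", "r", "c", "d"),
                 c("a", "b", "c", "d", "b", "e", "e", "h", "d", "e"))
  pre <- c("h", "a", "e", "d", "r")
  mu <- 0.35
  expect_lt(gcc_fraction(fix, pre), mu)
  fin <- deletion_stage(fix, pre, mu)
  expect_false("r" %in% fin)
  expect_true(all(fin %in% pre))
  expect_lt(gcc_fraction(fix, as.character(fin)), mu)
  for (v in fin) expect_gte(gcc_fraction(fix, setdiff(fin, v)), mu)

  # already-minimal set comes back unchanged
  p4 <- g_path(4)
  expect_identical(as.character(deletion_stage(p4, "p002", mu = 0.6)), "p002")

  expect_error(deletion_stage(p4, character(0), mu = 0.1),
               "preselected")
})

test_that("full selection satisfies its postconditions deterministically", {
  bb <- g_barbell()
  s <- spreadrank_select(bb, mu = 0.46)
  expect_lt(s$q, 0.46)
  expect_setequal(s$selected, c("u1", "v1")) # the two clique hubs
  s2 <- spreadrank_select(bb, mu = 0.46)
  expect_identical(s$selected, s2$selected)

  g <- ba_graph(150, 2, seed = 21)
  a <- spreadrank_select(g, mu = 0.05)
  b <- spreadrank_select(g, mu = 0.05)
  expect_identical(a$selected, b$selected)
  expect_lt(a$q, 0.05)
  expect_true(all(a$selected %in% a$preselected))
  expect_lte(length(a$selected), length(a$preselected))
})

test_that("regular graphs fall back to a degree-based selection", {
  s <- spreadrank_select(g_cycle(20), mu = 0.2)
  expect_lt(s$q, 0.2)
  expect_gte(length(s$selected), 4)
  expect_null(s$scores)
})

test_that("a smaller threshold never preselects fewer nodes", {
  # the addition stage's pick sequence does not depend on mu, so its output
  # for a smaller threshold is a (weak) superset prefix extension; the
  # greedy deletion stage carries no such guarantee
  for (seed in c(2, 8)) {
    g <- ba_graph(120, 2, seed = seed)
    pres <- lapply(c(0.02, 0.05, 0.1, 0.2), function(mu)
      spreadrank_select(g, mu = mu)$preselected)
    sizes <- lengths(pres)
    expect_true(all(diff(sizes) <= 0))
    for (i in 1:3) expect_identical(pres[[i]][seq_along(pres[[i + 1]])],
                                    pres[[i + 1]])
  }
})

test_that("tidy and glance summarise the selection", {
  g <- ba_graph(80, 2, seed = 13)
  s <- spreadrank_select(g, mu = 0.1)
  td <- tidy(s)
  expect_identical(td$node, s$preselected)
  expect_identical(td$node[td$kept], s$selected[order(match(s$selected, td$node))])
  gl <- glance(s)
  expect_equal(gl$n_selected, length(s$selected))
  expect_lt(gl$q, gl$mu)
})
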
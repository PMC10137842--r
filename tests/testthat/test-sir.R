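test_that("beta = 0 gives Pr = |seeds|/N exactly", {
  g <- ba_graph(40, 2, seed = 1)
  seeds <- c("1", "2", "3")
  r <- sir_run(g, beta = 0, gamma = 0.5, infected = seeds, seed = 7)
  expect_equal(r$pr, 3 / 40)
  ens <- sir_ensemble(g, beta = 0, gamma = 0.5, infected = seeds,
                      runs = 5, seed = 7)
  expect_equal(ens$pr_mean, 3 / 40)
  expect_equal(ens$pr_sd, 0)
})

test_that("beta = gamma = 1 floods exactly the seeded components", {
  st <- g_star(4)
  r <- sir_run(st, beta = 1, gamma = 1, infected = "c0", seed = 1)
  expect_equal(r$pr, 1)
  expect_equal(r$steps, 2)
  expect_equal(r$trajectory$i, c(1, 4, 0))
  expect_equal(r$trajectory$r, c(0, 1, 5))

  two <- g_edges(c("a", "b", "x", "y"), c("b", "c", "y", "z"))
  r2 <- sir_run(two, beta = 1, gamma = 1, infected = "a", seed = 1)
  expect_equal(r2$pr, 3 / 6) # the seeded component has 3 of 6 nodes

  g <- ba_graph(60, 3, seed = 9) # connected by construction
  ens <- sir_ensemble(g, beta = 1, gamma = 1, infected = "5", runs = 3, seed = 2)
  expect_equal(ens$pr_mean, 1)
  expect_equal(ens$pr_sd, 0)
})

test_that("S + I + R is conserved at every step and R is monotone", {
  g <- ba_graph(80, 2, seed = 3)
  for (s in 1:5) {
    r <- sir_run(g, beta = 0.2, gamma = 0.3, infected = c("1", "7"), seed = s)
    tr <- r$trajectory
    expect_true(all(tr$s + tr$i + tr$r == 80))
    expect_true(all(diff(tr$r) >= 0))
    expect_true(all(diff(tr$s) <= 0))
    expect_equal(tr$i[nrow(tr)], 0)
  }
})

test_that("SIR runs are reproducible under a fixed seed", {
  g <- ba_graph(60, 2, seed = 8)
  a <- sir_run(g, 0.1, 0.05, infected = "2", seed = 123)
  b <- sir_run(g, 0.1, 0.05, infected = "2", seed = 123)
  expect_identical(a$trajectory, b$trajectory)

  e1 <- spreading_experiment(g, c("1", "2"), c(0.05, 0.1), gamma = 0.05,
                             runs = 10, seed = 11)
  e2 <- spreading_experiment(g, c("1", "2"), c(0.05, 0.1), gamma = 0.05,
                             runs = 10, seed = 11)
  expect_identical(e1, e2)
})

test_that("SIR input validation catches bad configurations", {
  g <- g_triangle()
  expect_error(sir_run(g, beta = 1.2, gamma = 0.1, infected = "a"), "beta")
  expect_error(sir_run(g, beta = 0.1, gamma = -1, infected = "a"), "gamma")
  expect_error(sir_run(g, 0.1, 0.1, infected = character(0)), "non-empty")
  expect_error(sir_run(g, 0.1, 0.1, infected = "a", recovered = "a"),
               "disjoint")
  expect_error(sir_run(g, 0.1, 0.1, infected = "zz"), "not in network")
  expect_error(immunization_experiment(g, c("a", "b", "c"), 0.1), "every node")
  expect_error(immunization_experiment(g, "a", 0.1, infect_fraction = 0),
               "infect_fraction")
})

test_that("spreading grid at beta = 0 returns the seed fraction column", {
  g <- ba_graph(50, 2, seed = 6)
  tab <- spreading_experiment(g, c("1", "2"), beta_grid = 0, gamma = 0.1,
                              runs = 5, seed = 3)
  expect_equal(tab$mean_pr, 2 / 50)
  expect_equal(tab$sd_pr, 0)
})

test_that("immunization counts only infection-acquired recoveries", {
  # immune hub isolates every leaf: no spread is possible at all
  st <- g_star(9)
  tab <- immunization_experiment(st, "c0", beta_grid = 1, gamma = 1,
                                 infect_fraction = 0.3, runs = 8, seed = 5)
  expect_equal(tab$mean_pr, ceiling(0.3 * 9) / 10)
  expect_equal(tab$sd_pr, 0)

  # no immunity, beta = 0: exactly the initially infected recover
  tab0 <- immunization_experiment(st, character(0), beta_grid = 0, gamma = 1,
                                  infect_fraction = 0.3, runs = 4, seed = 5)
  expect_equal(tab0$mean_pr, ceiling(0.3 * 10) / 10)
})

test_that("ensemble trajectory padding carries the final state", {
  g <- g_star(4)
  ens <- sir_ensemble(g, beta = 1, gamma = 1, infected = "c0",
                      runs = 4, seed = 1)
  tr <- ens$trajectory
  expect_equal(tr$r[nrow(tr)], 5)
  expect_true(all(abs(tr$s + tr$i + tr$r - 5) < 1e-12))
})

test_that("tidy/glance/autoplot work on SIR objects", {
  g <- ba_graph(40, 2, seed = 2)
  ens <- sir_ensemble(g, 0.1, 0.1, infected = "1", runs = 5, seed = 4)
  expect_identical(tidy(ens), ens$trajectory)
  gl <- glance(ens)
  expect_equal(gl$runs, 5)
  p <- autoplot(ens)
  expect_s3_class(p, "ggplot")
  r <- sir_run(g, 0.1, 0.1, infected = "1", seed = 1)
  expect_named(glance(r), c("n_nodes", "beta", "gamma", "pr", "steps", "extinct"))
})
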
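# Small hand-checkable graphs, built fresh per call.

g_edges <- function(from, to) {
  as_spread_network(data.frame(from = from, to = to))
}

g_triangle <- function() g_edges(c("a", "b", "c"), c("b", "c", "a"))

g_star <- function(n_leaves = 4) {
  g_edges(rep("c0", n_leaves), paste0("l", seq_len(n_leaves)))
}

g_path <- function(n) {
  lab <- sprintf("p%03d", seq_len(n))
  g_edges(lab[-n], lab[-1])
}

g_cycle <- function(n) {
  lab <- sprintf("c%03d", seq_len(n))
  g_edges(lab, lab[c(2:n, 1)])
}

# Two K5 cliques whose first members are joined through a single bridge node.
g_barbell <- function() {
  k5 <- function(prefix) {
    cl <- combn(paste0(prefix, 1:5), 2)
    data.frame(from = cl[1, ], to = cl[2, ])
  }
  bridge <- data.frame(from = c("u1", "v1"), to = c("bb", "bb"))
  as_spread_network(rbind(k5("u"), k5("v"), bridge))
}

# Random simple graph with character labels (uniform G(n, p)).
g_random <- function(n, p, seed = NULL) er_graph(n, p, seed = seed)

edge_key <- function(net) {
  el <- igraph::as_edgelist(net)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
}
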
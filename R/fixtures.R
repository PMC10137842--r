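#' Barabasi-Albert scale-free network generator
#'
#' Preferential attachment with a clique seed: the first `m` nodes form a
#' complete graph, and each subsequent node attaches to `m` distinct existing
#' nodes sampled with probability proportional to current degree. The result
#' is simple and has exactly `choose(m, 2) + m * (n - m)` edges. Scale-free
#' graphs of this kind are the reference topology for the spread-centrality
#' method, which assumes a small population of above-average-degree hubs.
#'
#' @param n Number of nodes (`n > m`).
#' @param m Edges attached per new node (and seed-clique size).
#' @param seed Optional integer seed; fixed seed gives a deterministic graph.
#' @return An undirected simple `igraph` with node labels `"1" ... "n"`.
#' @examples
#' g <- ba_graph(100, 2, seed = 7)
#' graph_summary(g)
#' @export
ba_graph <- function(n, m, seed = NULL) {
  if (m < 1) abort("`m` must be >= 1")
  if (m >= n) abort("`m` must be smaller than `n`")
  with_local_seed(seed, {
    deg <- integer(n)
    from <- integer(0); to <- integer(0)
    if (m > 1) {
      cl <- utils::combn(m, 2)
      from <- cl[1, ]; to <- cl[2, ]
      deg[1:m] <- m - 1
    }
    for (v in seq(m + 1, n)) {
      prev <- seq_len(v - 1)
      w <- if (v == m + 1 && m == 1) 1L
           else sample(prev, m, prob = pmax(deg[prev], 1e-12))
      from <- c(from, rep(v, m)); to <- c(to, w)
      deg[w] <- deg[w] + 1L
      deg[v] <- m
    }
    as_spread_network(data.frame(from = as.character(from),
                                 to = as.character(to)))
  })
}

#' Erdos-Renyi random graph (robustness fixture)
#'
#' A `G(n, p)` graph, used only as a non-scale-free contrast in robustness
#' tests; the spread-centrality method targets scale-free topologies.
#'
#' @param n Number of nodes.
#' @param p Edge probability.
#' @param seed Optional integer seed.
#' @return An undirected simple `igraph` with labels `"1" ... "n"`.
#' @export
er_graph <- function(n, p, seed = NULL) {
  with_local_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- as.character(seq_len(n))
    as_spread_network(g)
  })
}

#' Hand-checkable bridged two-cluster toy network
#'
#' A fixed 18-node graph: two 6-cliques (`a1..a6`, `b1..b6`), two pendant
#' leaves on each cluster hub (`a7`, `a8` on `a1`; `b7`, `b8` on `b1`), and a
#' two-node bridge path `a1 - x1 - x2 - b1`. Removing the bridge nodes
#' `{x1, x2}` splits the graph into exactly two components, and the cluster
#' hubs `a1`, `b1` are the highest-degree local vital nodes. Byte-identical
#' across calls.
#'
#' @return An undirected simple `igraph`.
#' @export
toy_bridge_graph <- function() {
  clique <- function(prefix) {
    cl <- utils::combn(paste0(prefix, 1:6), 2)
    data.frame(from = cl[1, ], to = cl[2, ])
  }
  extra <- data.frame(
    from = c("a1", "a1", "b1", "b1", "a1", "x1", "x2"),
    to   = c("a7", "a8", "b7", "b8", "x1", "x2", "b1")
  )
  as_spread_network(rbind(clique("a"), clique("b"), extra))
}
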
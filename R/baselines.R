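ranking_tibble <- function(net, method, score) {
  lab <- node_labels(net)
  deg <- as.numeric(igraph::degree(net))
  ord <- order(-score, -deg, lab, method = "radix")
  tibble(method = method, rank = seq_along(lab),
         node = lab[ord], score = score[ord])
}

#' Baseline node rankings
#'
#' The five standard centralities used as comparison baselines for the
#' spread-centrality selection, each returned as a tidy ranking (one row per
#' node, best first, ties broken by score then degree then label):
#'
#' * `degree_ranking()` — node degree.
#' * `betweenness_ranking()` — shortest-path betweenness (Brandes
#'   accumulation, endpoints excluded, shortest-path multiplicities
#'   weighted).
#' * `kshell_ranking()` — k-shell (coreness) index from iterative peeling of
#'   nodes of degree `<= k`; degree breaks ties within a shell.
#' * `eigenvector_ranking()` — principal eigenvector of the adjacency matrix
#'   of the giant component (power iteration to tolerance 1e-10,
#'   L2-normalized, non-negative); nodes outside the giant component score 0.
#' * `voterank_ranking()` — iterative voting: every node starts with voting
#'   ability 1; each round the node with the largest sum of neighbour
#'   abilities is elected, its ability drops to 0 permanently, and each of
#'   its neighbours loses `1 / <k>` ability (floored at 0), where `<k>` is
#'   the average degree.
#'
#' @inheritParams write_edgelist
#' @return A tibble of class `node_ranking`: `method`, `rank`, `node`,
#'   `score`.
#' @name baseline_rankings
#' @examples
#' g <- ba_graph(50, 2, seed = 3)
#' head(degree_ranking(g))
NULL

#' @rdname baseline_rankings
#' @export
degree_ranking <- function(net) {
  net <- as_spread_network(net)
  ranking_tibble(net, "degree", as.numeric(igraph::degree(net)))
}

#' @rdname baseline_rankings
#' @export
betweenness_ranking <- function(net) {
  net <- as_spread_network(net)
  ranking_tibble(net, "betweenness", as.numeric(igraph::betweenness(net)))
}

#' @rdname baseline_rankings
#' @export
kshell_ranking <- function(net) {
  net <- as_spread_network(net)
  ranking_tibble(net, "kshell", as.numeric(igraph::coreness(net)))
}

#' @rdname baseline_rankings
#' @param tol Power-iteration convergence tolerance.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @export
eigenvector_ranking <- function(net, tol = 1e-10, max_iter = 100000) {
  net <- as_spread_network(net)
  n <- igraph::vcount(net)
  comp <- igraph::components(net)
  gcc_idx <- which(comp$membership == which.max(comp$csize))
  score <- numeric(n)
  if (length(gcc_idx) >= 2) {
    sub <- igraph::induced_subgraph(net, gcc_idx)
    A <- igraph::as_adjacency_matrix(sub, sparse = TRUE)
    x <- rep(1 / sqrt(length(gcc_idx)), length(gcc_idx))
    converged <- FALSE
    # iterate with A + I: same principal eigenvector, but the shift breaks
    # the +/- lambda degeneracy of bipartite components so the iteration
    # cannot oscillate
    for (it in seq_len(max_iter)) {
      y <- as.numeric(A %*% x) + x
      y <- y / sqrt(sum(y^2))
      if (max(abs(y - x)) < tol) { x <- y; converged <- TRUE; break }
      x <- y
    }
    if (!converged) abort("power iteration did not converge")
    score[gcc_idx] <- abs(x)
  }
  ranking_tibble(net, "eigenvector", score)
}

#' @rdname baseline_rankings
#' @param k Number of nodes to elect (default: all).
#' @export
voterank_ranking <- function(net, k = NULL) {
  net <- as_spread_network(net)
  lab <- node_labels(net)
  n <- length(lab)
  if (is.null(k)) k <- n
  if (k <= 0) abort("`k` must be positive")
  if (k > n) abort("`k` cannot exceed the number of nodes")
  adj <- adj_list(net)
  delta <- 1 / average_degree(net)
  ability <- rep(1, n)
  electable <- rep(TRUE, n)
  deg <- as.numeric(igraph::degree(net))
  elected <- integer(0)
  elected_score <- numeric(0)
  for (round in seq_len(k)) {
    votes <- vapply(seq_len(n), function(v) sum(ability[adj[[v]]]), numeric(1))
    votes[!electable] <- -Inf
    ord <- order(-votes, -deg, lab, method = "radix")
    win <- ord[1]
    elected <- c(elected, win)
    elected_score <- c(elected_score, votes[win])
    electable[win] <- FALSE
    ability[win] <- 0
    nb <- adj[[win]]
    ability[nb] <- pmax(0, ability[nb] - delta)
  }
  rest <- setdiff(seq_len(n), elected)
  if (length(rest) > 0) {
    votes <- vapply(rest, function(v) sum(ability[adj[[v]]]), numeric(1))
    ord <- order(-votes, -deg[rest], lab[rest], method = "radix")
    rest <- rest[ord]
    rest_score <- votes[ord]
  } else rest_score <- numeric(0)
  tibble(method = "voterank", rank = seq_len(n),
         node = lab[c(elected, rest)],
         score = c(elected_score, rest_score))
}

#' Rank nodes by any supported method
#'
#' Dispatcher over the five baselines and the spread-centrality ranking
#' itself, so that every method feeds the same downstream SIR harness.
#' For `method = "spreadrank"` the vital nodes come first in spread-
#' centrality order, followed by the non-vital nodes by degree.
#'
#' @inheritParams write_edgelist
#' @param method One of `"degree"`, `"betweenness"`, `"kshell"`,
#'   `"eigenvector"`, `"voterank"`, `"spreadrank"`.
#' @param ... Passed to the method-specific ranking function.
#' @return A ranking tibble (`method`, `rank`, `node`, `score`).
#' @export
rank_nodes <- function(net, method = c("degree", "betweenness", "kshell",
                                       "eigenvector", "voterank",
                                       "spreadrank"), ...) {
  method <- match.arg(method)
  net <- as_spread_network(net)
  switch(method,
    degree = degree_ranking(net),
    betweenness = betweenness_ranking(net),
    kshell = kshell_ranking(net),
    eigenvector = eigenvector_ranking(net, ...),
    voterank = voterank_ranking(net, ...),
    spreadrank = {
      sc <- spread_centrality(net, ...)
      tibble(method = "spreadrank", rank = seq_len(nrow(sc)),
             node = sc$node, score = sc$sc)
    })
}

#' Top-k node set of a ranking
#'
#' @param ranking A ranking tibble from [rank_nodes()] or the individual
#'   ranking functions.
#' @param k Number of nodes to take (0 gives the empty set).
#' @return Character vector: the first `k` ranked nodes.
#' @export
top_k_set <- function(ranking, k) {
  if (k < 0 || k > nrow(ranking)) abort("`k` must be between 0 and N")
  head(ranking$node, k)
}
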
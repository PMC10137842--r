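#' Attenuate working spread-centrality values around a picked node
#'
#' After a node is picked into the influential set, the working centrality of
#' its neighbourhood is damped so that subsequent picks avoid overlapping
#' influence ranges: the picked node's working value is set to 0, first-order
#' neighbours (graph distance exactly 1) retain 1/2 of their current value,
#' and second-order neighbours (distance exactly 2) retain 3/4. Factors
#' compound multiplicatively across successive picks; already-selected nodes
#' stay at 0.
#'
#' @inheritParams write_edgelist
#' @param working Named numeric vector of current working centrality values.
#' @param picked Name of the node being picked (must have the maximal working
#'   value among non-selected candidates; not enforced here).
#' @param selected Labels already selected in earlier rounds.
#' @return The updated named working vector.
#' @export
attenuate_scores <- function(working, net, picked, selected = character()) {
  net <- as_spread_network(net)
  picked <- as.character(picked)
  check_nodes(net, picked, "picked")
  if (picked %in% selected) abort("`picked` was already selected")
  lab <- node_labels(net)
  d <- as.numeric(igraph::distances(net, v = picked, to = lab))
  names(d) <- lab
  working[picked] <- 0
  first <- intersect(names(working), lab[d == 1])
  second <- intersect(names(working), lab[d == 2])
  working[first] <- working[first] * 0.5
  working[second] <- working[second] * 0.75
  working[names(working) %in% selected] <- 0
  working
}

# Ordered fallback pool: nodes ranked by degree desc then label.
degree_pool <- function(net, exclude = character()) {
  lab <- node_labels(net)
  deg <- igraph::degree(net)
  pool <- setdiff(lab, exclude)
  pool[order(-deg[match(pool, lab)], pool, method = "radix")]
}

pick_max <- function(working, deg, selected) {
  cand <- setdiff(names(working), selected)
  if (length(cand) == 0) return(NULL)
  w <- working[cand]
  ord <- order(-w, -deg[cand], cand, method = "radix")
  cand[ord[1]]
}

#' Node addition stage of the influential-set selection
#'
#' Repeatedly picks the candidate with the maximal working spread centrality
#' (ties broken by degree then label), attenuates its neighbourhood
#' ([attenuate_scores()]), and recomputes the residual giant-component
#' fraction `q = gcc_fraction(net, S)`; stops the first time `q < mu`.
#' If the vital-node candidates are exhausted while `q >= mu` (possible on
#' non-scale-free topologies), the pool is extended with the remaining nodes
#' ranked by degree and the loop continues.
#'
#' @inheritParams write_edgelist
#' @param scores A [spread_centrality()] table for `net`.
#' @param mu Giant-component threshold in `(0, 1)`.
#' @return Character vector: the preselected set in pick order, with
#'   attributes `q` (final fraction) and `q_history`.
#' @export
addition_stage <- function(net, scores, mu) {
  net <- as_spread_network(net)
  if (!(mu > 0 && mu < 1)) abort("`mu` must lie in (0, 1)")
  lab <- node_labels(net)
  deg <- setNames(as.numeric(igraph::degree(net)), lab)
  vital <- scores$node[scores$vital]
  working <- setNames(scores$sc[match(vital, scores$node)], vital)
  adj <- adj_list(net)
  n <- length(lab)
  keep <- rep(TRUE, n)
  selected <- character()
  q_hist <- numeric()
  q <- 1
  extended <- length(working) == 0
  if (extended)
    working <- setNames(deg[degree_pool(net)], degree_pool(net))
  repeat {
    pick <- pick_max(working, deg, selected)
    if (is.null(pick)) {
      if (extended) break # every node selected; q is 0 by now
      extended <- TRUE
      pool <- degree_pool(net, exclude = selected)
      working <- c(working, setNames(deg[pool], pool))
      next
    }
    working <- attenuate_scores(working, net, pick, selected)
    selected <- c(selected, pick)
    keep[match(pick, lab)] <- FALSE
    q <- if (any(keep)) cpp_gcc_size(adj, keep) / n else 0
    q_hist <- c(q_hist, q)
    if (q < mu) break
  }
  structure(selected, q = q, q_history = q_hist)
}

#' Node deletion stage of the influential-set selection
#'
#' Prunes redundant nodes from the preselected set: at each round, the node
#' whose restoration to the network has the least impact on the giant
#' component (minimal `gcc_fraction(net, S \ {i})`, ties by lowest spread
#' centrality then label) is found; if even after restoring it the giant
#' component stays below `mu`, the node is dropped from `S`. The loop stops
#' when restoring the best candidate would break the threshold.
#'
#' @inheritParams addition_stage
#' @param preselected Character vector from [addition_stage()]; must satisfy
#'   `gcc_fraction(net, preselected) < mu`.
#' @param scores Optional [spread_centrality()] table used for tie-breaks.
#' @return The pruned set (subset of `preselected`, original pick order),
#'   with attribute `q`.
#' @export
deletion_stage <- function(net, preselected, mu, scores = NULL) {
  net <- as_spread_network(net)
  if (!(mu > 0 && mu < 1)) abort("`mu` must lie in (0, 1)")
  preselected <- as.character(preselected)
  check_nodes(net, preselected, "preselected")
  lab <- node_labels(net)
  n <- length(lab)
  adj <- adj_list(net)
  keep <- !(lab %in% preselected)
  q <- if (any(keep)) cpp_gcc_size(adj, keep) / n else 0
  if (q >= mu)
    abort("`preselected` does not satisfy gcc_fraction(net, preselected) < mu")
  sc <- if (is.null(scores)) setNames(rep(0, n), lab)
        else setNames(scores$sc[match(lab, scores$node)], lab)
  S <- preselected
  repeat {
    if (length(S) == 0) break
    qs <- vapply(S, function(i) {
      k <- keep
      k[match(i, lab)] <- TRUE
      cpp_gcc_size(adj, k) / n
    }, numeric(1))
    ord <- order(qs, sc[S], S, method = "radix")
    best <- S[ord[1]]
    if (qs[ord[1]] >= mu) break
    S <- setdiff(S, best)
    keep[match(best, lab)] <- TRUE
    q <- qs[ord[1]]
  }
  structure(S, q = q)
}

#' Select an influential spreader set
#'
#' Full pipeline: compute the path-reachability spread centrality, run the
#' addition stage (max-centrality picking with neighbourhood attenuation
#' until the residual giant component drops below `mu * N`), then the
#' deletion stage (greedy pruning of redundant picks). The result is a
#' compact node set whose removal fragments the network below the threshold
#' — good immunization targets, and when used as seeds, widely spread
#' initial spreaders.
#'
#' On networks with fewer than two local vital nodes (e.g. regular graphs)
#' the centrality is undefined and the selection falls back to a pure
#' degree ranking with the same attenuation and stopping rules.
#'
#' @inheritParams write_edgelist
#' @param mu Giant-component threshold in `(0, 1)`; default 0.01.
#' @param l_max Maximum valid-path edge-length for the centrality.
#' @return An object of class `spreadrank_set`: list with `selected` (final
#'   set, pick order), `preselected`, `q`, `q_preselected`, `mu`, `l_max`,
#'   `scores` (the centrality table or `NULL` under the degree fallback),
#'   and `n_nodes`.
#' @examples
#' g <- ba_graph(100, 2, seed = 5)
#' s <- spreadrank_select(g, mu = 0.1)
#' s
#' @export
spreadrank_select <- function(net, mu = 0.01, l_max = 6) {
  net <- as_spread_network(net)
  if (igraph::vcount(net) < 3) abort("need at least 3 nodes")
  if (!(mu > 0 && mu < 1)) abort("`mu` must lie in (0, 1)")
  scores <- tryCatch(spread_centrality(net, l_max = l_max),
                     spreadrank_too_few_vital = function(e) NULL)
  if (is.null(scores)) {
    lab <- node_labels(net)
    deg <- as.numeric(igraph::degree(net))
    scores_tbl <- tibble(node = lab, degree = deg, vital = FALSE,
                         pd = 0, pn = 0, pl = NA_real_, sc = 0)
    pre <- addition_stage(net, scores_tbl, mu)
  } else {
    scores_tbl <- scores
    pre <- addition_stage(net, scores_tbl, mu)
  }
  fin <- deletion_stage(net, pre, mu, scores = scores_tbl)
  structure(
    list(
      selected = as.character(fin), preselected = as.character(pre),
      q = attr(fin, "q"), q_preselected = attr(pre, "q"),
      mu = mu, l_max = as.integer(l_max),
      scores = if (is.null(scores)) NULL else scores_tbl,
      n_nodes = igraph::vcount(net)
    ),
    class = "spreadrank_set"
  )
}

#' @export
print.spreadrank_set <- function(x, ...) {
  cat(sprintf(
    "<spreadrank_set> %d node(s) selected of %d (preselected %d)\n",
    length(x$selected), x$n_nodes, length(x$preselected)))
  cat(sprintf("  residual giant component q = %.4f < mu = %g\n", x$q, x$mu))
  cat("  selected:", paste(head(x$selected, 12), collapse = ", "),
      if (length(x$selected) > 12) "..." else "", "\n")
  invisible(x)
}

#' @describeIn spreadrank_select Tidy the selection: one row per preselected
#'   node with pick order, final-set membership and spread centrality.
#' @param x A `spreadrank_set`.
#' @param ... Unused.
#' @export
tidy.spreadrank_set <- function(x, ...) {
  sc <- if (is.null(x$scores)) rep(NA_real_, length(x$preselected))
        else x$scores$sc[match(x$preselected, x$scores$node)]
  tibble(
    node = x$preselected,
    pick = seq_along(x$preselected),
    kept = x$preselected %in% x$selected,
    sc = sc
  )
}

#' @describeIn spreadrank_select One-row summary of the selection.
#' @export
glance.spreadrank_set <- function(x, ...) {
  tibble(
    n_nodes = x$n_nodes, n_selected = length(x$selected),
    n_preselected = length(x$preselected),
    q = x$q, q_preselected = x$q_preselected, mu = x$mu, l_max = x$l_max
  )
}
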
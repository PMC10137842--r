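#' Local vital nodes of a network
#'
#' Local vital nodes are the nodes whose degree strictly exceeds the network's
#' average degree `2E/N`. In scale-free networks these are the few hubs that
#' dominate local spreading; spread centrality is defined only on this set.
#'
#' @inheritParams write_edgelist
#' @return Character vector of node labels, sorted by degree descending then
#'   label ascending. May be empty (e.g. for regular graphs, where no degree
#'   exceeds the mean).
#' @export
local_vital_nodes <- function(net) {
  net <- as_spread_network(net)
  if (igraph::vcount(net) < 2) abort("need at least 2 nodes")
  deg <- igraph::degree(net)
  lab <- node_labels(net)
  vital <- lab[deg > average_degree(net)]
  vital[order(-deg[match(vital, lab)], vital, method = "radix")]
}

#' Enumerate valid spread paths between two nodes
#'
#' A valid spread path is a simple path (no repeated node) of edge-length at
#' most `l_max` (default 6, the six-degrees horizon beyond which paths are
#' considered ineffective for spreading). Paths are returned exactly once, in
#' lexicographic order of their node sequences.
#'
#' @inheritParams write_edgelist
#' @param from,to Distinct node labels.
#' @param l_max Maximum path edge-length (>= 1).
#' @return A `path_set` object: list with `source`, `target`, `l_max`,
#'   `paths` (list of character vectors) and `k = length(paths)`.
#' @examples
#' tri <- as_spread_network(data.frame(c("a", "b", "c"), c("b", "c", "a")))
#' enumerate_valid_paths(tri, "a", "b")
#' @export
enumerate_valid_paths <- function(net, from, to, l_max = 6) {
  net <- as_spread_network(net)
  from <- as.character(from); to <- as.character(to)
  check_nodes(net, c(from, to))
  if (identical(from, to)) abort("`from` and `to` must be distinct nodes")
  if (l_max < 1) abort("`l_max` must be at least 1")
  lab <- node_labels(net)
  raw <- cpp_bounded_paths(adj_list(net), match(from, lab), match(to, lab),
                           as.integer(l_max))
  ps <- list(
    source = from, target = to, l_max = as.integer(l_max),
    paths = lapply(raw, function(p) lab[p]), k = length(raw)
  )
  class(ps) <- "path_set"
  ps
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf("<path_set> %s -> %s: %d valid path(s), l_max = %d\n",
              x$source, x$target, x$k, x$l_max))
  for (p in head(x$paths, 10)) cat(" ", paste(p, collapse = " - "), "\n")
  if (x$k > 10) cat("  ...\n")
  invisible(x)
}

#' @export
as_tibble.path_set <- function(x, ...) {
  tibble(
    source = x$source, target = x$target,
    path = x$paths,
    length = vapply(x$paths, function(p) length(p) - 1L, integer(1))
  )
}

#' Path diversity of a set of paths between two nodes
#'
#' The mean, over all `choose(k, 2)` unordered pairs of valid paths, of the
#' interior non-overlap `1 - 2 w / (d1 + d2)`, where `d1`, `d2` are the
#' interior-node counts of the two paths and `w` the number of interior nodes
#' they share. Fully interior-disjoint routes score 1, identical routes 0.
#' A pair of one direct edge and one longer path shares nothing and scores 1.
#' With fewer than two paths there is no redundancy to measure and the
#' diversity is 0.
#'
#' @param ps A `path_set` from [enumerate_valid_paths()], or a bare list of
#'   node-sequence vectors.
#' @return A number in `[0, 1]`.
#' @export
path_diversity <- function(ps) {
  paths <- if (inherits(ps, "path_set")) ps$paths else ps
  k <- length(paths)
  if (k < 2) return(0)
  interiors <- lapply(paths, function(p) p[-c(1, length(p))])
  total <- 0
  for (a in 1:(k - 1)) {
    for (b in (a + 1):k) {
      d1 <- length(interiors[[a]])
      d2 <- length(interiors[[b]])
      w <- length(intersect(interiors[[a]], interiors[[b]]))
      total <- total + if (d1 + d2 == 0) 1 else 1 - 2 * w / (d1 + d2)
    }
  }
  min(1, max(0, total / choose(k, 2)))
}

#' Per-node path-reachability indices
#'
#' For a vital node `i`, averages the pairwise indices over the other
#' `l - 1` vital targets: `pd` is the mean pairwise path diversity, `pn` the
#' mean number of valid paths, and `pl` the pooled mean edge-length of all
#' valid paths from `i` (total length / total count). Target pairs with no
#' valid path contribute 0 to `pd`/`pn` and no length terms; a node that
#' reaches no target at all gets the worst-case `pl = l_max + 1`.
#'
#' @inheritParams write_edgelist
#' @param vital Character vector of vital nodes (at least 2).
#' @param node One element of `vital`.
#' @param l_max Maximum path edge-length.
#' @return A one-row tibble: `node`, `pd`, `pn`, `pl`.
#' @export
node_reachability <- function(net, vital, node, l_max = 6) {
  net <- as_spread_network(net)
  vital <- as.character(vital); node <- as.character(node)
  check_nodes(net, vital, "vital")
  if (!node %in% vital) abort("`node` must be one of the vital nodes")
  if (length(vital) < 2) abort("need at least 2 vital nodes")
  lab <- node_labels(net)
  targets <- setdiff(vital, node)
  st <- cpp_source_stats(adj_list(net), match(node, lab),
                         match(targets, lab), as.integer(l_max))
  summarise_reachability(st$pd, st$k, st$totlen, l_max) |>
    dplyr::mutate(node = node, .before = 1)
}

summarise_reachability <- function(pd_ij, k_ij, totlen_ij, l_max) {
  ktot <- sum(k_ij)
  tibble(
    pd = mean(pd_ij),
    pn = mean(k_ij),
    pl = if (ktot > 0) sum(totlen_ij) / ktot else l_max + 1
  )
}

#' Min-max normalization to the unit interval
#'
#' `(x - min) / (max - min)` elementwise. When all values are equal the map is
#' undefined; all outputs are set to 0.5, which preserves symmetry between
#' indistinguishable nodes.
#'
#' @param x Non-empty numeric vector of finite values.
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_norm <- function(x) {
  if (length(x) == 0) abort("`x` must be non-empty")
  if (any(!is.finite(x))) abort("`x` must be finite (no NaN/NA/Inf)")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0.5, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Spread centrality of all nodes
#'
#' The path-reachability centrality: for each local vital node `i`,
#' `sc_i = (norm(pd_i) + norm(pn_i) + norm(1 / pl_i)) / 3`, where the
#' min-max normalizations are taken across the vital-node population.
#' High spread centrality means node `i` reaches the other hubs through many,
#' short, mutually non-overlapping routes. Non-vital nodes carry `sc = 0`.
#'
#' @inheritParams write_edgelist
#' @param l_max Maximum valid-path edge-length (default 6).
#' @return A tibble of class `spread_centrality` with one row per node:
#'   `node`, `degree`, `vital` (logical), `pd`, `pn`, `pl`, `sc`; rows
#'   ordered by `sc` descending, ties by degree descending then label.
#'   Attribute `vital_ranking` holds the vital nodes in rank order.
#' @examples
#' g <- ba_graph(60, 2, seed = 11)
#' head(spread_centrality(g))
#' @export
spread_centrality <- function(net, l_max = 6) {
  net <- as_spread_network(net)
  lab <- node_labels(net)
  deg <- igraph::degree(net)
  vital <- local_vital_nodes(net)
  if (length(vital) < 2)
    abort(paste("fewer than 2 local vital nodes: spread centrality is",
                "undefined; fall back to a degree ranking"),
          class = "spreadrank_too_few_vital")
  st <- cpp_vital_pair_stats(adj_list(net), match(vital, lab),
                             as.integer(l_max))
  per <- purrr::map_dfr(seq_along(vital), function(i) {
    summarise_reachability(st$pd[i, -i], st$k[i, -i], st$totlen[i, -i], l_max)
  })
  sc <- (minmax_norm(per$pd) + minmax_norm(per$pn) + minmax_norm(1 / per$pl)) / 3
  out <- tibble(
    node = lab, degree = as.numeric(deg), vital = lab %in% vital,
    pd = 0, pn = 0, pl = NA_real_, sc = 0
  )
  idx <- match(vital, lab)
  out$pd[idx] <- per$pd
  out$pn[idx] <- per$pn
  out$pl[idx] <- per$pl
  out$sc[idx] <- sc
  out <- out[order(-out$sc, -out$degree, out$node, method = "radix"), ]
  structure(out, class = c("spread_centrality", class(tibble())),
            vital_ranking = out$node[out$vital], l_max = as.integer(l_max))
}
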
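# Independent oracles, written straight from first principles and kept free
# of the package's C++ kernels: recursive R path enumeration, naive pairwise
# path diversity, union-find components, all-pairs BFS, and an exhaustive
# betweenness accumulator. Deliberately slow; used on tiny inputs only.

# All simple paths from `from` to `to` with edge-length <= lmax, by plain
# recursive DFS over igraph neighbor lists.
oracle_paths <- function(net, from, to, lmax) {
  out <- list()
  recurse <- function(path) {
    u <- path[length(path)]
    if (length(path) - 1 > lmax) return()
    if (u == to && length(path) > 1) {
      out[[length(out) + 1]] <<- path
      return()
    }
    if (length(path) - 1 == lmax) return()
    nb <- igraph::neighbors(net, u)$name
    for (w in setdiff(nb, path)) recurse(c(path, w))
  }
  recurse(from)
  out
}

path_key <- function(paths) sort(vapply(paths, paste, character(1), collapse = "|"))

# Naive pairwise path diversity: mean over all C(k,2) pairs of
# 1 - 2w / (d1 + d2) on interior nodes.
oracle_pd <- function(paths) {
  k <- length(paths)
  if (k < 2) return(0)
  interior <- lapply(paths, function(p) p[-c(1, length(p))])
  total <- 0
  for (a in seq_len(k - 1)) {
    ia <- interior[[a]]; d1 <- length(ia)
    for (b in (a + 1):k) {
      ib <- interior[[b]]; d2 <- length(ib)
      w <- sum(ia %in% ib)
      total <- total + if (d1 + d2 == 0) 1 else 1 - 2 * w / (d1 + d2)
    }
  }
  min(1, max(0, total / choose(k, 2)))
}

# Straight-from-the-equations reachability indices of one vital node.
oracle_reachability <- function(net, vital, i, lmax) {
  targets <- setdiff(vital, i)
  pd <- pn <- numeric(length(targets))
  totlen <- totk <- 0
  for (t in seq_along(targets)) {
    ps <- oracle_paths(net, i, targets[t], lmax)
    pd[t] <- oracle_pd(ps)
    pn[t] <- length(ps)
    totk <- totk + length(ps)
    totlen <- totlen + sum(vapply(ps, length, integer(1)) - 1)
  }
  list(pd = mean(pd), pn = mean(pn),
       pl = if (totk > 0) totlen / totk else lmax + 1)
}

# Full spread-centrality recomputation from the oracle indices.
oracle_spread_centrality <- function(net, lmax = 6) {
  deg <- igraph::degree(net)
  lab <- igraph::V(net)$name
  avg <- 2 * igraph::ecount(net) / igraph::vcount(net)
  vital <- lab[deg > avg]
  stopifnot(length(vital) >= 2)
  idx <- lapply(vital, function(v) oracle_reachability(net, vital, v, lmax))
  pd <- vapply(idx, `[[`, numeric(1), "pd")
  pn <- vapply(idx, `[[`, numeric(1), "pn")
  pl <- vapply(idx, `[[`, numeric(1), "pl")
  mm <- function(x) {
    if (max(x) == min(x)) rep(0.5, length(x))
    else (x - min(x)) / (max(x) - min(x))
  }
  tibble::tibble(node = vital, pd = pd, pn = pn, pl = pl,
                 sc = (mm(pd) + mm(pn) + mm(1 / pl)) / 3)
}

# Second independent route for larger graphs: igraph's own C simple-path
# enumerator plus the same naive pairwise equations. Still never touches the
# package's kernels.
oracle_paths_ig <- function(net, from, to, lmax) {
  lapply(igraph::all_simple_paths(net, from = from, to = to, cutoff = lmax),
         function(x) x$name)
}

oracle_spread_centrality_ig <- function(net, lmax = 6) {
  deg <- igraph::degree(net)
  lab <- igraph::V(net)$name
  vital <- lab[deg > 2 * igraph::ecount(net) / igraph::vcount(net)]
  stopifnot(length(vital) >= 2)
  idx <- lapply(vital, function(v) {
    targets <- setdiff(vital, v)
    pd <- pn <- numeric(length(targets))
    totlen <- totk <- 0
    for (t in seq_along(targets)) {
      ps <- oracle_paths_ig(net, v, targets[t], lmax)
      pd[t] <- oracle_pd(ps)
      pn[t] <- length(ps)
      totk <- totk + length(ps)
      totlen <- totlen + sum(lengths(ps) - 1)
    }
    list(pd = mean(pd), pn = mean(pn),
         pl = if (totk > 0) totlen / totk else lmax + 1)
  })
  pd <- vapply(idx, `[[`, numeric(1), "pd")
  pn <- vapply(idx, `[[`, numeric(1), "pn")
  pl <- vapply(idx, `[[`, numeric(1), "pl")
  mm <- function(x) {
    if (max(x) == min(x)) rep(0.5, length(x))
    else (x - min(x)) / (max(x) - min(x))
  }
  tibble::tibble(node = vital, pd = pd, pn = pn, pl = pl,
                 sc = (mm(pd) + mm(pn) + mm(1 / pl)) / 3)
}

# Union-find connected components (labels -> component id).
oracle_components <- function(net) {
  lab <- igraph::V(net)$name
  parent <- stats::setNames(lab, lab)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  el <- igraph::as_edgelist(net)
  for (e in seq_len(nrow(el))) {
    ra <- find(el[e, 1]); rb <- find(el[e, 2])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(lab, find, character(1))
}

# Single-source BFS distances over labels (Inf when unreachable).
oracle_bfs <- function(net, src) {
  lab <- igraph::V(net)$name
  dist <- stats::setNames(rep(Inf, length(lab)), lab)
  dist[src] <- 0
  frontier <- src
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- character()
    for (u in frontier) nxt <- c(nxt, igraph::neighbors(net, u)$name)
    nxt <- unique(nxt[is.infinite(dist[nxt])])
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# Mean clustering (degree < 2 counts as 0) and mean GCC distance, from
# first principles.
oracle_summary <- function(net) {
  lab <- igraph::V(net)$name
  cc <- vapply(lab, function(v) {
    nb <- igraph::neighbors(net, v)$name
    if (length(nb) < 2) return(0)
    links <- 0
    for (a in seq_len(length(nb) - 1)) for (b in (a + 1):length(nb))
      if (igraph::are_adjacent(net, nb[a], nb[b])) links <- links + 1
    2 * links / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  comp <- oracle_components(net)
  sizes <- table(comp)
  gcc <- names(comp)[comp == names(sizes)[which.max(sizes)]]
  dsum <- 0; npair <- 0
  for (v in gcc) {
    d <- oracle_bfs(net, v)[setdiff(gcc, v)]
    dsum <- dsum + sum(d); npair <- npair + length(d)
  }
  list(mean_clustering = mean(cc), mean_distance = dsum / npair)
}

# Exhaustive shortest-path betweenness: enumerate every simple path per
# ordered pair, keep the shortest, credit interior nodes 1/count.
oracle_betweenness <- function(net) {
  lab <- igraph::V(net)$name
  n <- length(lab)
  bt <- stats::setNames(rep(0, n), lab)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    ps <- oracle_paths(net, lab[a], lab[b], n)
    if (length(ps) == 0) next
    lens <- vapply(ps, length, integer(1))
    sp <- ps[lens == min(lens)]
    for (p in sp) {
      inner <- p[-c(1, length(p))]
      bt[inner] <- bt[inner] + 1 / length(sp)
    }
  }
  bt
}
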
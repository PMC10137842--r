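#' Coerce to a canonical undirected simple network
#'
#' All user-facing functions accept either an [igraph][igraph::igraph-package]
#' graph or a two-column edge data frame. Internally the graph is made simple
#' (self-loops and parallel edges collapsed), undirected, and its vertices are
#' ordered by label (radix/C-locale sort) so that every downstream computation
#' is deterministic and independent of input edge order.
#'
#' @param x An undirected `igraph` object or a data frame whose first two
#'   columns are the edge endpoints (coerced to character labels).
#' @return An undirected simple `igraph` with character vertex names in
#'   canonical (label-sorted) order.
#' @examples
#' g <- as_spread_network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' igraph::vcount(g)
#' @export
as_spread_network <- function(x) {
  if (igraph::is_igraph(x)) {
    g <- x
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
    if (is.null(igraph::V(g)$name))
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  } else if (is.data.frame(x)) {
    if (ncol(x) < 2) abort("edge data frame needs at least two columns")
    from <- as.character(x[[1]])
    to <- as.character(x[[2]])
    keep <- from != to
    if (!all(keep)) warn(sprintf("dropped %d self-loop edge(s)", sum(!keep)))
    verts <- sort(unique(c(from, to)), method = "radix")
    g <- igraph::graph_from_data_frame(
      data.frame(from = from[keep], to = to[keep]),
      directed = FALSE, vertices = verts
    )
    g <- igraph::simplify(g)
  } else {
    abort("`x` must be an igraph object or an edge data frame")
  }
  if (igraph::vcount(g) < 1) abort("network must contain at least one node")
  ord <- order(igraph::V(g)$name, method = "radix")
  igraph::permute(g, order(ord))
}

node_labels <- function(net) igraph::V(net)$name

# 1-based adjacency list in canonical vertex order, neighbours sorted
# ascending by index (hence by label) — the layout the C++ kernels expect.
adj_list <- function(net) {
  lapply(igraph::as_adj_list(net, mode = "all"), function(v) sort(as.integer(v)))
}

check_nodes <- function(net, nodes, arg = "nodes") {
  miss <- setdiff(nodes, node_labels(net))
  if (length(miss) > 0)
    abort(sprintf("%s not in network: %s", arg,
                  paste(head(miss, 5), collapse = ", ")))
  invisible(nodes)
}

#' Read an undirected network from a whitespace-separated edge list
#'
#' One edge per line, `u v` (extra tokens beyond the first two are ignored);
#' lines starting with `#` or `%` and blank lines are comments. Duplicate
#' edges (in either orientation) collapse to one; self-loop lines are dropped
#' with a warning. Node labels are kept as strings.
#'
#' @param source Path to a file, or a connection / character vector of lines.
#' @return An undirected simple `igraph` network.
#' @seealso [write_edgelist()]
#' @export
read_edgelist <- function(source) {
  lines <- if (is.character(source) && length(source) == 1 && file.exists(source))
    readLines(source) else if (inherits(source, "connection"))
    readLines(source) else as.character(source)
  raw_idx <- seq_along(lines)
  keep <- !grepl("^\\s*($|#|%)", lines)
  lines <- lines[keep]
  raw_idx <- raw_idx[keep]
  if (length(lines) == 0) abort("empty edge list: no edges found")
  toks <- strsplit(trimws(lines), "\\s+")
  nt <- lengths(toks)
  if (any(nt < 2))
    abort(sprintf("malformed edge list: line %d has a single token",
                  raw_idx[which(nt < 2)[1]]))
  from <- vapply(toks, `[[`, character(1), 1)
  to <- vapply(toks, `[[`, character(1), 2)
  loops <- from == to
  if (any(loops))
    warn(sprintf("dropped %d self-loop line(s) (e.g. line %d)",
                 sum(loops), raw_idx[which(loops)[1]]))
  if (all(loops)) abort("empty edge list: all lines were self-loops")
  as_spread_network(data.frame(from = from[!loops], to = to[!loops]))
}

#' Write a network as a whitespace-separated edge list
#'
#' @param net Network (igraph or edge data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(net, path) {
  net <- as_spread_network(net)
  el <- igraph::as_edgelist(net)
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

#' Average degree of a network
#'
#' Returns `2 |E| / N`, the mean number of links per node. This is the
#' threshold used to define local vital nodes.
#'
#' @inheritParams write_edgelist
#' @return A single number.
#' @export
average_degree <- function(net) {
  net <- as_spread_network(net)
  2 * igraph::ecount(net) / igraph::vcount(net)
}

#' Connected components as a tidy table
#'
#' @inheritParams write_edgelist
#' @return A tibble with columns `node`, `component` (integer id, largest
#'   component first) and `size`.
#' @export
graph_components <- function(net) {
  net <- as_spread_network(net)
  comp <- igraph::components(net)
  ord <- order(-comp$csize, seq_along(comp$csize))
  relab <- match(seq_along(comp$csize), ord)
  tibble(
    node = node_labels(net),
    component = relab[comp$membership],
    size = comp$csize[comp$membership]
  ) |> dplyr::arrange(.data$component, .data$node)
}

#' Relative size of the giant component after node removal
#'
#' The dismantling statistic `q = |GCC(G[V \ removed])| / N`, where `N` is the
#' node count of the *original* network. `q < mu` is the stopping criterion of
#' the influential-set selection.
#'
#' @inheritParams write_edgelist
#' @param removed Character vector of node labels to delete (may be empty).
#' @return `q`, a number in `[0, 1]`; 0 when every node is removed.
#' @examples
#' p4 <- as_spread_network(data.frame(c("1", "2", "3"), c("2", "3", "4")))
#' gcc_fraction(p4, removed = "2")
#' @export
gcc_fraction <- function(net, removed = character()) {
  net <- as_spread_network(net)
  removed <- as.character(removed)
  check_nodes(net, removed, "removed")
  n <- igraph::vcount(net)
  keep <- !(node_labels(net) %in% removed)
  if (!any(keep)) return(0)
  cpp_gcc_size(adj_list(net), keep) / n
}

#' Descriptive summary statistics of a network
#'
#' @inheritParams write_edgelist
#' @return A one-row tibble: `nodes`, `edges`, `mean_degree` (`2E/N`),
#'   `max_degree`, `mean_clustering` (local clustering, counted as 0 for
#'   nodes of degree < 2), and `mean_distance` (mean shortest-path length
#'   over pairs within the giant component).
#' @export
graph_summary <- function(net) {
  net <- as_spread_network(net)
  if (igraph::vcount(net) < 2) abort("summary needs at least 2 nodes")
  deg <- igraph::degree(net)
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  comp <- igraph::components(net)
  gcc <- igraph::induced_subgraph(
    net, which(comp$membership == which.max(comp$csize)))
  md <- if (igraph::vcount(gcc) >= 2) igraph::mean_distance(gcc) else NA_real_
  tibble(
    nodes = igraph::vcount(net),
    edges = igraph::ecount(net),
    mean_degree = 2 * igraph::ecount(net) / igraph::vcount(net),
    max_degree = max(deg),
    mean_clustering = mean(cc),
    mean_distance = md
  )
}
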
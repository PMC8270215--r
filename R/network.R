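#' The interaction-network container
#'
#' An `interaction_network` wraps an undirected [igraph][igraph::igraph] graph
#' over gene symbols together with a cached sparse binary adjacency matrix.
#' It is the universe for every statistic in the package: propagation, module
#' growth, overlap enrichment and proximity all draw their node sets, degrees
#' and distances from it.
#'
#' Invariants enforced at construction: no self-loops, no duplicate
#' (unordered) edges, every confidence weight in `[0, 1]`, no isolated nodes.
#'
#' @param edges A data frame with columns `from`, `to` and `weight`
#'   (confidence in `[0, 1]`).
#' @return An object of class `interaction_network`.
#' @examples
#' net <- interaction_network(
#'   tibble::tibble(from = c("A", "B"), to = c("B", "C"), weight = 1)
#' )
#' network_nodes(net)
#' @export
interaction_network <- function(edges) {
  edges <- as_tibble(edges)
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  edges <- edges |>
    mutate(
      from = as.character(.data$from),
      to = as.character(.data$to),
      a = pmin(.data$from, .data$to),
      b = pmax(.data$from, .data$to)
    ) |>
    filter(.data$a != .data$b) |>
    distinct(.data$a, .data$b, .keep_all = TRUE) |>
    select(from = "a", to = "b", "weight") |>
    arrange(.data$from, .data$to)
  if (nrow(edges) == 0L) {
    abort("network has no edges", class = "netindic_empty_network")
  }
  if (any(edges$weight < 0 | edges$weight > 1)) {
    abort("edge weights must lie in [0, 1]")
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  nodes <- sort(igraph::V(g)$name)
  g <- igraph::permute(g, match(igraph::V(g)$name, nodes))
  idx <- cbind(
    match(edges$from, nodes),
    match(edges$to, nodes)
  )
  adj <- sparseMatrix(
    i = c(idx[, 1], idx[, 2]), j = c(idx[, 2], idx[, 1]),
    x = 1, dims = c(length(nodes), length(nodes)),
    dimnames = list(nodes, nodes)
  )
  structure(
    list(graph = g, nodes = nodes, edges = edges, adjacency = adj),
    class = "interaction_network"
  )
}

#' @rdname interaction_network
#' @param network An `interaction_network`.
#' @export
network_nodes <- function(network) network$nodes

#' @rdname interaction_network
#' @export
network_edges <- function(network) network$edges

#' @rdname interaction_network
#' @export
network_degree <- function(network) {
  setNames(as.integer(rowSums(network$adjacency)), network$nodes)
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(
    "<interaction_network> ", length(x$nodes), " nodes, ",
    nrow(x$edges), " edges\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.interaction_network <- function(x, ...) x$edges

#' @export
glance.interaction_network <- function(x, ...) {
  deg <- network_degree(x)
  tibble(
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    mean_degree = mean(deg),
    max_degree = max(deg)
  )
}

neighbors_of <- function(network, nodes) {
  idx <- match(intersect(nodes, network$nodes), network$nodes)
  if (length(idx) == 0L) return(character())
  hits <- rowSums(network$adjacency[, idx, drop = FALSE]) > 0
  network$nodes[hits]
}

assert_in_network <- function(network, nodes, what = "node") {
  missing <- setdiff(nodes, network$nodes)
  if (length(missing) > 0L) {
    abort(
      paste0(
        what, "(s) not in network: ",
        paste(missing, collapse = ", ")
      ),
      class = "netindic_missing_nodes"
    )
  }
  invisible(TRUE)
}

#' A subnetwork around an origin node set
#'
#' A `subnetwork` is a node set with designated origin nodes (the drug
#' target(s) or a disease's seed genes) and a construction tag saying which
#' side of the comparison it came from.
#'
#' @param nodes Character vector of member gene symbols.
#' @param origin Character vector of origin nodes; must be a subset of
#'   `nodes`.
#' @param construction `"target"` or `"disease"`.
#' @return An object of class `subnetwork`.
#' @export
subnetwork <- function(nodes, origin, construction = c("target", "disease")) {
  construction <- match.arg(construction)
  nodes <- unique(as.character(nodes))
  origin <- unique(as.character(origin))
  if (!all(origin %in% nodes)) {
    abort("origin nodes must be a subset of subnetwork nodes")
  }
  structure(
    list(nodes = nodes, origin = origin, construction = construction),
    class = "subnetwork"
  )
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(
    "<subnetwork:", x$construction, "> ", length(x$nodes), " nodes (",
    length(x$origin), " origin)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.subnetwork <- function(x, ...) {
  tibble(node = x$nodes, is_origin = x$nodes %in% x$origin)
}
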
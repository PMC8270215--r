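#' Hypergeometric connectivity p-value of a candidate node
#'
#' Under the null that a candidate node's neighbours are drawn at random
#' from the rest of the network, the size of the intersection between its
#' neighbourhood and the current module follows a hypergeometric
#' distribution. The returned upper-tail probability `P(X >= k_s)` uses
#' `k_s = |neighbours(node) ∩ current_set|` observed links, `deg(node)`
#' draws, `|current_set|` successes in a population of all network nodes
#' except the candidate itself.
#'
#' @param node A gene symbol not in `current_set`.
#' @param current_set Character vector: the current module members.
#' @param network An [interaction_network].
#' @return A probability in `(0, 1]`.
#' @export
connectivity_pvalue <- function(node, current_set, network) {
  stopifnot(!node %in% current_set)
  assert_in_network(network, node)
  nbrs <- neighbors_of(network, node)
  k_s <- length(intersect(nbrs, current_set))
  n_nodes <- length(network$nodes)
  phyper(
    k_s - 1L,
    m = length(current_set),
    n = n_nodes - 1L - length(current_set),
    k = length(nbrs),
    lower.tail = FALSE
  )
}

#' Grow a disease module by iterative connectivity significance (DIAMOnD)
#'
#' Starting from a disease's genetically associated seed genes, repeatedly
#' adds the outside node whose links into the current module are most
#' hypergeometrically surprising ([connectivity_pvalue()]). Candidates are
#' the non-members with at least one edge into the module; ties on the
#' p-value are broken by lexicographic node id for determinism. Growth
#' stops after `n_iterations` additions (the module-size parameter; 200 is
#' the conventional putative size of a complete disease module on a
#' full-scale interactome) or when no candidate remains.
#'
#' Seeds absent from the network are dropped with a warning, mirroring the
#' catalog-intersection policy.
#'
#' @param network An [interaction_network].
#' @param seeds Character vector of seed genes.
#' @param n_iterations Number of nodes to add (default 200).
#' @return An `expansion_trace`: a tibble of the ordered additions with
#'   columns `node`, `pvalue`, `iteration`, `is_seed` (seeds listed first
#'   with iteration 0 and `NA` p-value), with the final [subnetwork] as
#'   attribute `"subnetwork"`.
#' @export
diamond_expand <- function(network, seeds, n_iterations = 200L) {
  seeds <- unique(as.character(seeds))
  stopifnot(n_iterations >= 0, length(seeds) > 0)
  dropped <- setdiff(seeds, network$nodes)
  if (length(dropped) > 0L) {
    warn(paste0(
      "dropping ", length(dropped), " seed(s) absent from the network: ",
      paste(dropped, collapse = ", ")
    ))
    seeds <- setdiff(seeds, dropped)
  }
  if (length(seeds) == 0L) {
    abort("no seeds remain in the network", class = "netindic_missing_nodes")
  }
  nodes <- network$nodes
  n_nodes <- length(nodes)
  adj <- network$adjacency
  deg <- rowSums(adj)
  member <- nodes %in% seeds
  # links from every node into the current module, updated incrementally
  links_in <- as.vector(adj %*% as.numeric(member))
  added <- character(0)
  added_p <- numeric(0)
  iter <- 0L
  while (iter < n_iterations) {
    cand <- which(!member & links_in > 0)
    if (length(cand) == 0L) break
    set_size <- sum(member)
    pvals <- phyper(
      links_in[cand] - 1,
      m = set_size,
      n = n_nodes - 1L - set_size,
      k = deg[cand],
      lower.tail = FALSE
    )
    pick <- cand[order(pvals, nodes[cand])[1]]
    iter <- iter + 1L
    added <- c(added, nodes[pick])
    added_p <- c(added_p, min(pvals))
    member[pick] <- TRUE
    links_in <- links_in + as.vector(adj[, pick])
  }
  trace <- bind_rows(
    tibble(node = sort(seeds), pvalue = NA_real_, iteration = 0L,
           is_seed = TRUE),
    tibble(node = added, pvalue = added_p,
           iteration = seq_along(added), is_seed = FALSE)
  )
  class(trace) <- c("expansion_trace", class(trace))
  attr(trace, "subnetwork") <- subnetwork(
    c(seeds, added), origin = seeds, construction = "disease"
  )
  trace
}

#' Extract the final subnetwork from an expansion trace
#'
#' @param trace An `expansion_trace` from [diamond_expand()].
#' @return The final disease [subnetwork].
#' @export
trace_subnetwork <- function(trace) attr(trace, "subnetwork")

#' @export
glance.expansion_trace <- function(x, ...) {
  tibble(
    n_seeds = sum(x$is_seed),
    n_added = sum(!x$is_seed),
    n_total = nrow(x),
    min_pvalue = suppressWarnings(min(x$pvalue, na.rm = TRUE))
  )
}
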
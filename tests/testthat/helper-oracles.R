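# Independent oracles used across the suite. Each is a deliberately naive
# reimplementation (enumeration, rescan, queue BFS) kept free of any package
# internals so that agreement is evidence, not tautology.

# upper-tail hypergeometric P(X >= k_obs) by direct combinatorial summation
oracle_hyper_tail <- function(k_obs, marked, draws, universe) {
  if (k_obs <= 0) return(1)
  j <- seq(k_obs, min(marked, draws))
  if (length(j) == 0 || k_obs > min(marked, draws)) return(0)
  sum(choose(marked, j) * choose(universe - marked, draws - j)) /
    choose(universe, draws)
}

# random connected-ish test graph as an edge tibble; isolated nodes are
# dropped by the network constructor
random_graph_edges <- function(n_nodes, edge_prob) {
  pairs <- t(utils::combn(n_nodes, 2))
  keep <- stats::runif(nrow(pairs)) < edge_prob
  if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
  ids <- sprintf("N%03d", seq_len(n_nodes))
  tibble::tibble(
    from = ids[pairs[keep, 1]],
    to = ids[pairs[keep, 2]],
    weight = 1
  )
}

random_network <- function(n_nodes, edge_prob) {
  interaction_network(random_graph_edges(n_nodes, edge_prob))
}

# adjacency list from a network, for oracles that must not touch igraph
oracle_adjlist <- function(network) {
  e <- network_edges(network)
  nodes <- network_nodes(network)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(e))) {
    adj[[e$from[i]]] <- c(adj[[e$from[i]]], e$to[i])
    adj[[e$to[i]]] <- c(adj[[e$to[i]]], e$from[i])
  }
  adj
}

# naive module expansion: rescans every candidate from scratch each round
oracle_diamond <- function(network, seeds, n_iterations) {
  adj <- oracle_adjlist(network)
  nodes <- names(adj)
  current <- sort(intersect(seeds, nodes))
  added <- character(0)
  for (iter in seq_len(n_iterations)) {
    members <- c(current, added)
    cand <- setdiff(nodes, members)
    cand <- cand[vapply(
      cand, function(v) length(intersect(adj[[v]], members)) > 0, logical(1)
    )]
    if (length(cand) == 0) break
    p <- vapply(cand, function(v) {
      oracle_hyper_tail(
        k_obs = length(intersect(adj[[v]], members)),
        marked = length(members),
        draws = length(adj[[v]]),
        universe = length(nodes) - 1
      )
    }, numeric(1))
    ord <- order(p, cand)
    added <- c(added, cand[ord[1]])
  }
  added
}

# queue-based breadth-first shortest-path distances from one source
oracle_bfs <- function(adj, source) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[source] <- 0
  queue <- source
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!is.finite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

oracle_distance_matrix <- function(network, from, to) {
  adj <- oracle_adjlist(network)
  out <- matrix(Inf, length(from), length(to),
                dimnames = list(from, to))
  for (s in from) out[s, ] <- oracle_bfs(adj, s)[to]
  out
}

# AUROC by exhaustive positive-negative pair counting, ties at half
oracle_auroc <- function(ranks_pos, ranks_neg) {
  total <- 0
  for (p in ranks_pos) {
    for (q in ranks_neg) {
      total <- total + (p < q) + 0.5 * (p == q)
    }
  }
  total / (length(ranks_pos) * length(ranks_neg))
}

# Holm step-down by the textbook formula, sorted then mapped back
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- cummax(pmin(1, (m - seq_len(m) + 1) * p[ord]))
  out <- numeric(m)
  out[ord] <- adj
  out
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
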
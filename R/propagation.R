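#' Propagation configuration
#'
#' Bundles the tunables of the iterative flow-propagation scheme: the
#' retention fraction `alpha` (how much flow keeps circulating through the
#' network versus being re-injected at the origin nodes), the L1 convergence
#' tolerance, and an iteration cap.
#'
#' @param alpha Retention fraction in `(0, 1)`. Default `0.5`.
#' @param tolerance Stop once the L1 norm of the update falls below this.
#'   Default `1e-6`.
#' @param max_iterations Iteration cap; non-convergence within it is
#'   reported, not fatal. Default `10000`.
#' @return A `propagation_config` list.
#' @export
propagation_config <- function(alpha = 0.5, tolerance = 1e-6,
                               max_iterations = 10000L) {
  stopifnot(alpha > 0, alpha < 1, tolerance > 0, max_iterations >= 1)
  structure(
    list(alpha = alpha, tolerance = tolerance,
         max_iterations = as.integer(max_iterations)),
    class = "propagation_config"
  )
}

#' Symmetrically degree-normalized adjacency matrix
#'
#' Entry (i, j) of the returned sparse matrix is `1 / sqrt(deg(i) * deg(j))`
#' for every edge i-j and zero elsewhere. The normalization compensates for
#' hub nodes picking up flow by chance; with it, the propagation fixed point
#' exists for any retention fraction below 1 (spectral radius at most 1).
#' Edge confidence weights are not used: adjacency is binary, only degrees
#' enter.
#'
#' @param network An [interaction_network].
#' @return A symmetric sparse `Matrix` with node-name dimnames.
#' @export
normalized_adjacency <- function(network) {
  adj <- network$adjacency
  deg <- rowSums(adj)
  stopifnot("isolated nodes cannot occur post-filtering" = all(deg > 0))
  d <- Diagonal(x = 1 / sqrt(deg))
  out <- d %*% adj %*% d
  dimnames(out) <- dimnames(adj)
  out
}

#' Iterative flow propagation from seed nodes
#'
#' Scores every network node by its proximity to the seed set under the
#' update `F_t = alpha * A' %*% F_{t-1} + (1 - alpha) * F_0`, where `A'` is
#' the degree-normalized adjacency ([normalized_adjacency()]) and `F_0`
#' assigns flow 1 to each seed and 0 elsewhere. Iteration stops when the L1
#' norm of the change drops below the configured tolerance.
#'
#' @param network An [interaction_network].
#' @param seeds Character vector of seed nodes (all must be in the network).
#' @param config A [propagation_config()].
#' @return A `flow_vector` tibble with columns `node`, `flow` and
#'   `is_seed`, sorted by decreasing flow, with attributes
#'   `iterations_used` and `converged`.
#' @examples
#' net <- interaction_network(
#'   tibble::tibble(from = "A", to = "B", weight = 1)
#' )
#' propagate(net, "A", propagation_config(alpha = 0.5))
#' @export
propagate <- function(network, seeds, config = propagation_config()) {
  seeds <- unique(as.character(seeds))
  stopifnot(length(seeds) > 0)
  assert_in_network(network, seeds, "seed")
  aprime <- normalized_adjacency(network)
  f0 <- as.numeric(network$nodes %in% seeds)
  f <- f0
  converged <- FALSE
  iters <- 0L
  for (i in seq_len(config$max_iterations)) {
    f_next <- as.vector(config$alpha * (aprime %*% f)) +
      (1 - config$alpha) * f0
    iters <- i
    if (sum(abs(f_next - f)) < config$tolerance) {
      f <- f_next
      converged <- TRUE
      break
    }
    f <- f_next
  }
  if (!converged) {
    warn(paste0(
      "propagation did not converge within ", config$max_iterations,
      " iterations (tolerance ", config$tolerance, ")"
    ))
  }
  new_flow_vector(network$nodes, f, seeds, iters, converged)
}

#' Closed-form propagation fixed point by direct linear solve
#'
#' Computes `F = (1 - alpha) * solve(I - alpha * A') %*% F_0` directly.
#' Intended as an exact cross-check for [propagate()] on small networks; a
#' dense solve guard refuses networks above 2000 nodes.
#'
#' @inheritParams propagate
#' @param alpha Retention fraction in `(0, 1)`.
#' @return A `flow_vector` tibble (with `converged = TRUE`,
#'   `iterations_used = 0`).
#' @export
propagate_exact <- function(network, seeds, alpha = 0.5) {
  seeds <- unique(as.character(seeds))
  stopifnot(alpha > 0, alpha < 1, length(seeds) > 0)
  assert_in_network(network, seeds, "seed")
  n <- length(network$nodes)
  if (n > 2000L) {
    abort("propagate_exact is a dense solve; limited to networks of at most 2000 nodes")
  }
  aprime <- as.matrix(normalized_adjacency(network))
  f0 <- as.numeric(network$nodes %in% seeds)
  f <- as.vector(solve(diag(n) - alpha * aprime, (1 - alpha) * f0))
  new_flow_vector(network$nodes, f, seeds, 0L, TRUE)
}

new_flow_vector <- function(nodes, flow, seeds, iterations, converged) {
  out <- tibble(node = nodes, flow = flow, is_seed = nodes %in% seeds) |>
    arrange(desc(.data$flow), .data$node)
  class(out) <- c("flow_vector", class(out))
  attr(out, "iterations_used") <- iterations
  attr(out, "converged") <- converged
  out
}

#' @export
tidy.flow_vector <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "flow_vector")
  out
}

#' @export
glance.flow_vector <- function(x, ...) {
  tibble(
    n_nodes = nrow(x),
    n_seeds = sum(x$is_seed),
    iterations_used = attr(x, "iterations_used"),
    converged = attr(x, "converged")
  )
}

#' Build the target subnetwork around one or more drug targets
#'
#' Runs flow propagation from the target gene(s), ranks all non-target
#' nodes by flow, takes the `top_k` best (ties at the cutoff broken by
#' lexicographic node id so the result is deterministic) and, by default,
#' adds the direct network neighbours of the targets and of the selected
#' top nodes. Target combinations are first-class: all targets inject flow
#' jointly.
#'
#' @param network An [interaction_network].
#' @param targets Character vector of target gene symbols.
#' @param config A [propagation_config()].
#' @param top_k Number of top-ranked neighbouring nodes to keep
#'   (default 200).
#' @param include_neighbors Also include direct neighbours of the targets
#'   and top nodes (default `TRUE`).
#' @return A [subnetwork] with `construction = "target"` and the flow
#'   vector attached as attribute `"flow"`.
#' @export
build_target_subnetwork <- function(network, targets,
                                    config = propagation_config(),
                                    top_k = 200L,
                                    include_neighbors = TRUE) {
  targets <- unique(as.character(targets))
  if (top_k <= 0) abort("top_k must be positive")
  assert_in_network(network, targets, "target")
  fv <- propagate(network, targets, config)
  ranked <- fv |>
    filter(!.data$is_seed) |>
    arrange(desc(.data$flow), .data$node)
  top <- head(ranked$node, top_k)
  nodes <- union(targets, top)
  if (include_neighbors) {
    nodes <- union(nodes, neighbors_of(network, nodes))
  }
  out <- subnetwork(nodes, origin = targets, construction = "target")
  attr(out, "flow") <- fv
  out
}
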
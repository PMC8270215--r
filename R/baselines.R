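#' Genetic-association baseline ranking
#'
#' Ranks diseases by their recorded gene-disease association score for the
#' target gene(s), in descending order; diseases with no recorded
#' association for any target score 0. For target combinations the
#' per-disease score is the maximum over the targets. Ties are broken by
#' lexicographic disease id.
#'
#' @param catalog A `disease_catalog`.
#' @param target Character vector of target gene symbol(s).
#' @return A tibble with columns `rank`, `disease_id`, `disease_name`,
#'   `mesh_id`, `assoc_score` and `score` (`= 1/rank`).
#' @export
genetic_association_rank <- function(catalog, target) {
  stopifnot(nrow(catalog) > 0, length(target) > 0)
  assoc <- map_dbl(catalog$scores, function(s) {
    hits <- s[intersect(names(s), target)]
    if (length(hits) == 0L) 0 else max(hits)
  })
  out <- tibble(
    disease_id = catalog$disease_id,
    disease_name = catalog$disease_name,
    mesh_id = catalog$mesh_id,
    assoc_score = assoc
  ) |>
    arrange(desc(.data$assoc_score), .data$disease_id) |>
    mutate(rank = row_number(), score = 1 / .data$rank) |>
    select(
      "rank", "disease_id", "disease_name", "mesh_id", "assoc_score", "score"
    )
  class(out) <- c("indication_ranking", class(out))
  attr(out, "variant") <- "genetic"
  out
}

pairwise_distances <- function(network, from, to) {
  igraph::distances(
    network$graph,
    v = from, to = to, weights = NA, algorithm = "unweighted"
  )
}

prepare_proximity_sets <- function(network, targets, disease_genes) {
  targets <- intersect(unique(as.character(targets)), network$nodes)
  disease_genes <- intersect(
    unique(as.character(disease_genes)), network$nodes
  )
  if (length(targets) == 0L || length(disease_genes) == 0L) {
    abort("targets and disease genes must intersect the network")
  }
  list(targets = targets, disease = disease_genes)
}

#' Closest network-proximity distance
#'
#' Average, over the disease genes, of the shortest-path distance to the
#' nearest drug target (unweighted hop counts). Disease genes unreachable
#' from every target are excluded with a message.
#'
#' @param network An [interaction_network].
#' @param targets Character vector of target genes.
#' @param disease_genes Character vector of disease-associated genes.
#' @return A non-negative number.
#' @export
closest_distance <- function(network, targets, disease_genes) {
  s <- prepare_proximity_sets(network, targets, disease_genes)
  d <- pairwise_distances(network, s$targets, s$disease)
  mins <- apply(d, 2, min)
  reachable <- is.finite(mins)
  if (!any(reachable)) {
    abort("no disease gene is reachable from any target")
  }
  if (any(!reachable)) {
    inform(paste0(
      sum(!reachable), " unreachable disease gene(s) excluded"
    ))
  }
  mean(mins[reachable])
}

#' Shortest (average) network-proximity distance
#'
#' Average shortest-path distance over all reachable target-disease gene
#' pairs.
#'
#' @inheritParams closest_distance
#' @return A non-negative number.
#' @export
shortest_distance <- function(network, targets, disease_genes) {
  s <- prepare_proximity_sets(network, targets, disease_genes)
  d <- pairwise_distances(network, s$targets, s$disease)
  vals <- d[is.finite(d)]
  if (length(vals) == 0L) {
    abort("no disease gene is reachable from any target")
  }
  if (any(!is.finite(d))) {
    inform(paste0(sum(!is.finite(d)), " unreachable pair(s) excluded"))
  }
  mean(vals)
}

#' Kernel network-proximity distance
#'
#' Exponentially down-weights long shortest paths:
#' `-(1/|T|) * sum over disease genes t of
#' log((1/|S|) * sum over targets s of exp(-(d(s, t) + 1)))`,
#' where `S` is the target set and `T` the disease gene set. Unreachable
#' pairs contribute `exp(-Inf) = 0`; a disease gene unreachable from every
#' target is excluded with a message.
#'
#' @inheritParams closest_distance
#' @return A non-negative number.
#' @export
kernel_distance <- function(network, targets, disease_genes) {
  s <- prepare_proximity_sets(network, targets, disease_genes)
  d <- pairwise_distances(network, s$targets, s$disease)
  inner <- apply(d, 2, function(col) mean(exp(-(col + 1))))
  reachable <- inner > 0
  if (!any(reachable)) {
    abort("no disease gene is reachable from any target")
  }
  if (any(!reachable)) {
    inform(paste0(
      sum(!reachable), " unreachable disease gene(s) excluded"
    ))
  }
  -mean(log(inner[reachable]))
}

proximity_measure <- function(measure) {
  switch(measure,
    closest = closest_distance,
    shortest = shortest_distance,
    kernel = kernel_distance
  )
}

#' Degree-binned random node sampling
#'
#' Draws a random node set matched to a reference set's degree
#' distribution: nodes are grouped into degree bins, each bin widened (by
#' merging with neighbouring degree values) until it holds at least
#' `min_bin_size` nodes, and each reference node is replaced by a random
#' draw from its bin (without replacement within one sample).
#'
#' @param network An [interaction_network].
#' @param reference Character vector whose degree profile to match.
#' @param min_bin_size Minimum nodes per bin before widening stops.
#' @return A character vector of sampled nodes, `length(reference)` long.
#' @keywords internal
sample_degree_matched <- function(network, reference, min_bin_size = 100L) {
  deg <- network_degree(network)
  bins <- degree_bins(deg, min_bin_size)
  picked <- character(0)
  for (node in reference) {
    pool <- setdiff(bins[[as.character(deg[[node]])]], picked)
    if (length(pool) == 0L) pool <- setdiff(network$nodes, picked)
    picked <- c(picked, pool[sample.int(length(pool), 1L)])
  }
  picked
}

# map each observed degree value to the member nodes of its (widened) bin
degree_bins <- function(deg, min_bin_size) {
  values <- sort(unique(deg))
  by_value <- split(names(deg), deg)
  bins <- list()
  for (v in values) {
    members <- by_value[[as.character(v)]]
    radius <- 0L
    while (length(members) < min_bin_size) {
      radius <- radius + 1L
      lo <- v - radius
      hi <- v + radius
      members <- names(deg)[deg >= lo & deg <= hi]
      if (lo <= min(values) && hi >= max(values)) break
    }
    bins[[as.character(v)]] <- members
  }
  bins
}

#' Proximity significance by degree-matched randomisation
#'
#' Compares an observed target-disease proximity against the distances
#' between the same targets and random gene sets of the same size and
#' degree profile as the disease genes: `z = (observed - mean) / sd` of the
#' random background. Negative z means the disease genes are closer to the
#' targets than degree-matched chance; diseases are ranked ascending by z.
#'
#' @inheritParams closest_distance
#' @param measure `"closest"`, `"shortest"` or `"kernel"`.
#' @param n_random Number of random background sets (`>= 2`; 1000 in a
#'   full-scale analysis, smaller for quick runs).
#' @param seed Integer seed for the background draws.
#' @param min_bin_size Degree-bin width control for
#'   [sample_degree_matched()].
#' @return A one-row tibble: `distance`, `background_mean`,
#'   `background_sd`, `zscore`, `n_random`.
#' @export
proximity_zscore <- function(network, targets, disease_genes,
                             measure = c("closest", "shortest", "kernel"),
                             n_random = 1000L, seed = 1L,
                             min_bin_size = 100L) {
  measure <- match.arg(measure)
  stopifnot(n_random >= 2)
  fn <- proximity_measure(measure)
  s <- prepare_proximity_sets(network, targets, disease_genes)
  observed <- suppressMessages(fn(network, s$targets, s$disease))
  background <- withr::with_seed(seed, {
    map_dbl(seq_len(n_random), function(i) {
      rand <- sample_degree_matched(network, s$disease, min_bin_size)
      suppressMessages(fn(network, s$targets, rand))
    })
  })
  mu <- mean(background)
  sdev <- sd(background)
  tibble(
    measure = measure,
    distance = observed,
    background_mean = mu,
    background_sd = sdev,
    zscore = if (sdev > 0) (observed - mu) / sdev else 0,
    n_random = as.integer(n_random)
  )
}

#' Proximity baseline ranking over a catalog
#'
#' Runs [proximity_zscore()] for every disease in the catalog (disease
#' genes = its seed genes) and ranks ascending by z-score (ties by raw
#' distance, then disease id). Raw distances are reported alongside.
#'
#' @inheritParams proximity_zscore
#' @param catalog A `disease_catalog`.
#' @return A tibble with columns `rank`, `disease_id`, `disease_name`,
#'   `mesh_id`, `distance`, `zscore` and `score` (`= 1/rank`).
#' @export
proximity_rank <- function(network, catalog, targets,
                           measure = c("closest", "shortest", "kernel"),
                           n_random = 1000L, seed = 1L,
                           min_bin_size = 100L) {
  measure <- match.arg(measure)
  res <- map2(catalog$disease_id, catalog$seeds, function(id, genes) {
    z <- proximity_zscore(
      network, targets, genes, measure,
      n_random = n_random,
      seed = seed + match(id, catalog$disease_id),
      min_bin_size = min_bin_size
    )
    mutate(z, disease_id = id)
  }) |>
    bind_rows()
  out <- res |>
    left_join(
      select(as_tibble(catalog), "disease_id", "disease_name", "mesh_id"),
      by = "disease_id"
    ) |>
    arrange(.data$zscore, .data$distance, .data$disease_id) |>
    mutate(rank = row_number(), score = 1 / .data$rank) |>
    select(
      "rank", "disease_id", "disease_name", "mesh_id",
      "distance", "zscore", "score"
    )
  class(out) <- c("indication_ranking", class(out))
  attr(out, "variant") <- paste0("proximity_", measure)
  out
}
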
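#' Generate a synthetic scale-free interactome
#'
#' Builds a connected preferential-attachment (Barabasi-Albert) graph, the
#' standard null model for the heavy-tailed degree distributions of
#' protein-interaction networks. Node ids are `G0001`, `G0002`, ...; all
#' edge confidences are 1.0 so any sensible threshold keeps every edge.
#'
#' @param n_nodes Number of nodes (`> attachment`).
#' @param attachment Edges each incoming node attaches with (`>= 1`).
#' @param seed Integer seed; the same seed reproduces the same graph.
#' @return An [interaction_network].
#' @export
generate_network <- function(n_nodes, attachment = 3L, seed = 1L) {
  stopifnot(n_nodes > attachment, attachment >= 1)
  g <- withr::with_seed(
    seed,
    igraph::sample_pa(n_nodes, m = attachment, directed = FALSE)
  )
  g <- igraph::simplify(g)
  ids <- sprintf("G%04d", seq_len(n_nodes))
  ends <- igraph::as_edgelist(g, names = FALSE)
  interaction_network(tibble(
    from = ids[ends[, 1]],
    to = ids[ends[, 2]],
    weight = 1.0
  ))
}

# grow a connected node set of the requested size by random-walk sampling;
# `start` anchors the walk, `forbidden` nodes are never entered
sample_connected_set <- function(network, size, start,
                                 forbidden = character(0),
                                 max_restarts = 50L) {
  for (attempt in seq_len(max_restarts)) {
    set <- start
    stuck <- FALSE
    while (length(set) < size) {
      frontier <- setdiff(neighbors_of(network, set), c(set, forbidden))
      if (length(frontier) == 0L) {
        stuck <- TRUE
        break
      }
      set <- c(set, frontier[sample.int(length(frontier), 1L)])
    }
    if (!stuck) return(set)
  }
  abort("could not grow a connected module of the requested size")
}

#' Plant a densified disease module in a network
#'
#' Emulates the tendency of disease-associated genes to interact with each
#' other and form localized modules: samples a connected node set by a
#' random walk, densifies it by adding missing intra-module edges with
#' probability `extra_edge_prob`, and designates a fraction of the members
#' as genetic seed genes with association scores drawn uniformly from
#' `[0.3, 1]` (informative but imperfect, so the genetic baseline has a
#' signal without being an oracle).
#'
#' @param network An [interaction_network].
#' @param module_size Number of module members.
#' @param extra_edge_prob Densification probability per missing
#'   intra-module pair.
#' @param seed_fraction Fraction of members designated genetic seeds
#'   (`ceiling(seed_fraction * module_size)` of them).
#' @param seed Integer seed.
#' @param start Optional anchor node for the walk; random if `NULL`.
#' @param forbidden Nodes the module must avoid.
#' @return A list: `network` (with the densification edges added),
#'   `module` (member nodes), `seeds` (genetic seed members) and `scores`
#'   (named association scores).
#' @export
plant_disease <- function(network, module_size = 20L,
                          extra_edge_prob = 0.3, seed_fraction = 0.5,
                          seed = 1L, start = NULL,
                          forbidden = character(0)) {
  stopifnot(
    module_size <= length(network$nodes),
    extra_edge_prob > 0, extra_edge_prob <= 1,
    seed_fraction > 0, seed_fraction <= 1
  )
  withr::with_seed(seed, {
    if (is.null(start)) {
      start <- sample(setdiff(network$nodes, forbidden), 1L)
    }
    module <- sample_connected_set(network, module_size, start, forbidden)
    pairs <- utils::combn(sort(module), 2L)
    existing <- paste(network$edges$from, network$edges$to)
    candidate <- paste(pairs[1, ], pairs[2, ])
    new_idx <- which(!(candidate %in% existing) &
                       runif(ncol(pairs)) < extra_edge_prob)
    edges <- network$edges
    if (length(new_idx) > 0L) {
      edges <- bind_rows(edges, tibble(
        from = pairs[1, new_idx], to = pairs[2, new_idx], weight = 1.0
      ))
    }
    n_seed <- ceiling(seed_fraction * module_size)
    seeds <- sort(sample(module, n_seed))
    scores <- setNames(runif(n_seed, 0.3, 1.0), seeds)
    list(
      network = interaction_network(edges),
      module = module, seeds = seeds, scores = scores
    )
  })
}

#' Benchmark generation parameters
#'
#' The study conditions of the synthetic planted-module benchmark: network
#' size and attachment, number of diseases, module size and densification,
#' seed fraction, and the target-module overlap fraction controlling how
#' strongly positive diseases are planted around the target.
#'
#' @param n_nodes,attachment Network size parameters
#'   ([generate_network()]).
#' @param n_diseases Number of diseases planted.
#' @param n_positives How many of them are true indications of the target.
#' @param module_size,extra_edge_prob,seed_fraction Module parameters
#'   ([plant_disease()]).
#' @param overlap Target-module overlap fraction in `[0, 1]`: each growth
#'   step of a positive module stays inside the target's direct
#'   neighbourhood with this probability (0 plants every module away from
#'   the target entirely, giving a null benchmark).
#' @return A named list of parameters.
#' @export
benchmark_params <- function(n_nodes = 500L, attachment = 3L,
                             n_diseases = 10L, n_positives = 1L,
                             module_size = 20L, extra_edge_prob = 0.3,
                             seed_fraction = 0.5, overlap = 0.8) {
  stopifnot(
    n_positives >= 0, n_positives <= n_diseases,
    overlap >= 0, overlap <= 1
  )
  list(
    n_nodes = n_nodes, attachment = attachment,
    n_diseases = n_diseases, n_positives = n_positives,
    module_size = module_size, extra_edge_prob = extra_edge_prob,
    seed_fraction = seed_fraction, overlap = overlap
  )
}

# grow a positive module biased toward the target's closed neighbourhood:
# each step enters N[target] with probability `overlap` when possible
sample_biased_set <- function(network, size, target, overlap) {
  closed <- union(target, neighbors_of(network, target))
  set <- if (runif(1) < overlap) target else {
    nb <- neighbors_of(network, target)
    nb[sample.int(length(nb), 1L)]
  }
  while (length(set) < size) {
    frontier <- setdiff(neighbors_of(network, set), set)
    if (length(frontier) == 0L) {
      abort("could not grow a connected module of the requested size")
    }
    near <- intersect(frontier, closed)
    pool <- if (length(near) > 0L && runif(1) < overlap) near else frontier
    set <- c(set, pool[sample.int(length(pool), 1L)])
  }
  set
}

#' Generate a complete planted-signal benchmark
#'
#' Builds a synthetic interactome, chooses a target gene, and plants
#' `n_diseases` disease modules: positive diseases are grown inside or
#' adjacent to the target's neighbourhood (per the overlap fraction) while
#' negative diseases avoid the target's closed neighbourhood entirely.
#' Which disease ids are positive is itself randomised so a null benchmark
#' carries no id bias. The result carries full ground truth, so pipeline
#' recovery (the planted positives ranking on top for the true target but
#' not for random targets) can be measured exactly.
#'
#' @param params A [benchmark_params()] list.
#' @param seed Integer seed; parameters + seed reproduce the benchmark
#'   byte for byte.
#' @return A `synthetic_benchmark` list: `network`, `catalog`
#'   (`disease_catalog`), `target`, `positives` (disease ids), `modules`
#'   (the planted node sets), `params`, `seed`.
#' @export
generate_benchmark <- function(params = benchmark_params(), seed = 1L) {
  net <- generate_network(params$n_nodes, params$attachment, seed = seed)
  withr::with_seed(seed + 1000L, {
    deg <- network_degree(net)
    # a moderately connected target: enough neighbours to host a module
    pool <- names(deg)[deg >= stats::quantile(deg, 0.7)]
    target <- sample(pool, 1L)
    pos_idx <- if (params$n_positives > 0) {
      sort(sample.int(params$n_diseases, params$n_positives))
    } else integer(0)
    module_seeds <- sample.int(1e7, params$n_diseases)
  })
  forbidden <- union(target, neighbors_of(net, target))
  entries <- vector("list", params$n_diseases)
  modules <- vector("list", params$n_diseases)
  for (i in seq_len(params$n_diseases)) {
    positive <- i %in% pos_idx && params$overlap > 0
    if (positive) {
      module <- withr::with_seed(
        module_seeds[i],
        sample_biased_set(net, params$module_size, target, params$overlap)
      )
      planted <- withr::with_seed(module_seeds[i] + 1L, {
        n_seed <- ceiling(params$seed_fraction * params$module_size)
        seeds <- sort(sample(module, n_seed))
        list(seeds = seeds,
             scores = setNames(runif(n_seed, 0.3, 1.0), seeds))
      })
      dens <- plant_module_edges(
        net, module, params$extra_edge_prob, module_seeds[i] + 2L
      )
      net <- dens
      planted <- c(list(module = module), planted)
    } else {
      res <- plant_disease(
        net,
        module_size = params$module_size,
        extra_edge_prob = params$extra_edge_prob,
        seed_fraction = params$seed_fraction,
        seed = module_seeds[i],
        forbidden = forbidden
      )
      net <- res$network
      planted <- res[c("module", "seeds", "scores")]
    }
    entries[[i]] <- tibble(
      disease_id = sprintf("D%02d", i),
      disease_name = sprintf("synthetic disease %02d", i),
      mesh_id = sprintf("MESH:%03d", i),
      seeds = list(planted$seeds),
      scores = list(planted$scores)
    )
    modules[[i]] <- planted$module
  }
  catalog <- disease_catalog(bind_rows(entries))
  structure(
    list(
      network = net,
      catalog = catalog,
      target = target,
      positives = sprintf("D%02d", pos_idx),
      modules = setNames(modules, sprintf("D%02d", seq_len(params$n_diseases))),
      params = params,
      seed = seed
    ),
    class = "synthetic_benchmark"
  )
}

# add the densification edges of a pre-chosen module (positive diseases,
# whose member sampling is handled separately from plant_disease)
plant_module_edges <- function(network, module, extra_edge_prob, seed) {
  withr::with_seed(seed, {
    pairs <- utils::combn(sort(module), 2L)
    existing <- paste(network$edges$from, network$edges$to)
    candidate <- paste(pairs[1, ], pairs[2, ])
    new_idx <- which(!(candidate %in% existing) &
                       runif(ncol(pairs)) < extra_edge_prob)
    edges <- network$edges
    if (length(new_idx) > 0L) {
      edges <- bind_rows(edges, tibble(
        from = pairs[1, new_idx], to = pairs[2, new_idx], weight = 1.0
      ))
    }
    interaction_network(edges)
  })
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat(
    "<synthetic_benchmark> ", length(x$network$nodes), " nodes, ",
    nrow(x$catalog), " diseases (", length(x$positives),
    " positive), target ", x$target, "\n",
    sep = ""
  )
  invisible(x)
}

#' Write a benchmark to disk in the reader dialects
#'
#' Emits `network.tsv` (STRING-dialect edge list), `diseases.tsv`
#' (gene-disease association table), `targets.txt` and `truth.tsv`
#' (target, disease id pairs) so that the files round-trip through
#' [read_interactions()] and [read_disease_catalog()].
#'
#' @param benchmark A `synthetic_benchmark`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(
    benchmark$network$edges |>
      rename(protein1 = "from", protein2 = "to",
             combined_score = "weight"),
    file.path(dir, "network.tsv")
  )
  assoc <- as_tibble(benchmark$catalog) |>
    select("disease_id", "disease_name", "mesh_id", "scores") |>
    mutate(scores = map(.data$scores, ~ tibble(
      geneSymbol = names(.x), score = unname(.x)
    ))) |>
    tidyr::unnest("scores") |>
    select(
      "geneSymbol", diseaseId = "disease_id",
      diseaseName = "disease_name", meshId = "mesh_id", "score"
    )
  readr::write_tsv(assoc, file.path(dir, "diseases.tsv"))
  writeLines(benchmark$target, file.path(dir, "targets.txt"))
  readr::write_tsv(
    tibble(target = benchmark$target, disease_id = benchmark$positives),
    file.path(dir, "truth.tsv")
  )
  invisible(dir)
}
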
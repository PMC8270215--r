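#' Hypergeometric overlap p-value between two subnetworks
#'
#' Probability of seeing at least the observed number of shared nodes when
#' the disease subnetwork's nodes are drawn without replacement from a
#' universe in which the target subnetwork's nodes are marked. The universe
#' is the full filtered interaction network.
#'
#' @param target_sub,disease_sub [subnetwork] objects (or plain character
#'   vectors of nodes).
#' @param universe_size Number of nodes in the universe; must be at least
#'   `|target ∪ disease|`.
#' @return The upper-tail probability in `(0, 1]`.
#' @export
overlap_pvalue <- function(target_sub, disease_sub, universe_size) {
  t_nodes <- subnetwork_nodes(target_sub)
  d_nodes <- subnetwork_nodes(disease_sub)
  if (length(t_nodes) == 0L || length(d_nodes) == 0L) {
    abort("target and disease subnetworks must be non-empty")
  }
  if (universe_size < length(union(t_nodes, d_nodes))) {
    abort("universe smaller than the union of the two subnetworks")
  }
  hyper_upper_tail(
    overlap = length(intersect(t_nodes, d_nodes)),
    marked = length(t_nodes),
    draws = length(d_nodes),
    universe = universe_size
  )
}

#' Seed-doubling weighted overlap p-value
#'
#' Variant of [overlap_pvalue()] in which every genetically associated seed
#' gene of the disease counts as two nodes, giving the seeds twice the
#' weight of the nodes added by module expansion: the disease draw, the
#' observed overlap and the universe are all enlarged by the seed
#' contribution before the same hypergeometric tail is computed. With no
#' designated seeds the variant reduces exactly to the plain test.
#'
#' @inheritParams overlap_pvalue
#' @return The upper-tail probability in `(0, 1]`.
#' @export
weighted_overlap_pvalue <- function(target_sub, disease_sub, universe_size) {
  t_nodes <- subnetwork_nodes(target_sub)
  d_nodes <- subnetwork_nodes(disease_sub)
  d_seeds <- if (inherits(disease_sub, "subnetwork")) disease_sub$origin else character(0)
  if (length(t_nodes) == 0L || length(d_nodes) == 0L) {
    abort("target and disease subnetworks must be non-empty")
  }
  if (universe_size < length(union(t_nodes, d_nodes))) {
    abort("universe smaller than the union of the two subnetworks")
  }
  n_seeds <- length(d_seeds)
  hyper_upper_tail(
    overlap = length(intersect(t_nodes, d_nodes)) +
      length(intersect(t_nodes, d_seeds)),
    marked = length(t_nodes),
    draws = length(d_nodes) + n_seeds,
    universe = universe_size + n_seeds
  )
}

subnetwork_nodes <- function(x) {
  if (inherits(x, "subnetwork")) x$nodes else unique(as.character(x))
}

hyper_upper_tail <- function(overlap, marked, draws, universe) {
  phyper(overlap - 1L, m = marked, n = universe - marked, k = draws,
         lower.tail = FALSE)
}

#' Holm step-down family-wise adjustment
#'
#' Adjusts a family of p-values by Holm's step-down rule: with the values
#' sorted ascending, the i-th adjusted value is
#' `max over j <= i of min(1, (m - j + 1) * p_(j))`, returned in the
#' original input order.
#'
#' @param pvalues Numeric vector of probabilities in `[0, 1]`.
#' @return Adjusted values in the input order.
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.04)) # 0.03 0.04 0.04
#' @export
holm_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "holm")
}

#' Seed-count-adjusted ranking metric
#'
#' Disease subnetworks grown from more genetically associated genes are
#' considered more reliable, so at equal enrichment p-value a disease with
#' more seeds should rank better. The metric is
#' `pvalue / log2(n_seeds + 1)` when `pvalue < 1`, and exactly 1 when
#' `pvalue = 1` (so completely unenriched diseases all sit at the metric
#' ceiling regardless of their seed count). Diseases are ranked by this
#' metric in ascending order.
#'
#' @param pvalue Enrichment p-value(s) in `[0, 1]`.
#' @param n_seeds Number of associated seed genes (`>= 1`); recycled.
#' @return The metric value(s), non-negative.
#' @export
ranking_metric <- function(pvalue, n_seeds) {
  stopifnot(all(pvalue >= 0 & pvalue <= 1))
  if (any(n_seeds < 1)) {
    abort("n_seeds must be at least 1 (log2(n_seeds + 1) must be positive)")
  }
  ifelse(pvalue < 1, pvalue / log2(n_seeds + 1), 1)
}

#' Rank all catalog diseases for a target subnetwork
#'
#' The end of the indication-expansion workflow: for every disease in the
#' catalog, grows its module by [diamond_expand()], computes the node-overlap
#' enrichment p-value against the target subnetwork (plain or seed-doubling
#' weighted variant) with the whole network as universe, Holm-adjusts the
#' p-value family, computes the seed-count-adjusted [ranking_metric()] from
#' the raw p-values, sorts ascending by metric (ties broken by raw p-value
#' then disease id), assigns dense ranks and the inverse-rank association
#' score, and finally collapses MeSH duplicates with
#' [deduplicate_by_mesh()].
#'
#' @param network An [interaction_network] (the universe).
#' @param target_sub The target [subnetwork].
#' @param catalog A `disease_catalog`.
#' @param variant `"plain"` or `"weighted"` (seed doubling).
#' @param module_iterations Expansion iterations per disease module
#'   (default 200).
#' @param modules Optional pre-computed named list of disease [subnetwork]s
#'   keyed by `disease_id` (modules are target-independent, so one
#'   computation serves every target; see [compute_disease_modules()]).
#' @param dedupe_mesh Collapse to one entry per MeSH id (default `TRUE`).
#' @return An `indication_ranking` tibble with columns `rank`,
#'   `disease_id`, `disease_name`, `mesh_id`, `n_seeds`, `pvalue`, `fdr`
#'   (Holm-adjusted), `metric` and `score` (`= 1/rank`).
#' @export
rank_indications <- function(network, target_sub, catalog,
                             variant = c("plain", "weighted"),
                             module_iterations = 200L,
                             modules = NULL,
                             dedupe_mesh = TRUE) {
  variant <- match.arg(variant)
  stopifnot(nrow(catalog) > 0)
  if (is.null(modules)) {
    modules <- compute_disease_modules(network, catalog, module_iterations)
  }
  universe <- length(network$nodes)
  pfun <- if (variant == "weighted") weighted_overlap_pvalue else overlap_pvalue
  pvals <- map_dbl(
    catalog$disease_id,
    function(id) pfun(target_sub, modules[[id]], universe)
  )
  out <- tibble(
    disease_id = catalog$disease_id,
    disease_name = catalog$disease_name,
    mesh_id = catalog$mesh_id,
    n_seeds = catalog$n_seeds,
    pvalue = pvals,
    fdr = holm_adjust(pvals),
    metric = ranking_metric(pvals, catalog$n_seeds)
  ) |>
    arrange(.data$metric, .data$pvalue, .data$disease_id) |>
    mutate(rank = row_number(), score = 1 / .data$rank) |>
    select(
      "rank", "disease_id", "disease_name", "mesh_id", "n_seeds",
      "pvalue", "fdr", "metric", "score"
    )
  class(out) <- c("indication_ranking", class(out))
  attr(out, "variant") <- variant
  if (dedupe_mesh) out <- deduplicate_by_mesh(out)
  out
}

#' Grow every disease module of a catalog once
#'
#' Disease modules do not depend on the target, so when several targets are
#' ranked against the same catalog (for instance against a random-target
#' background) the expansion can be computed once and shared.
#'
#' @inheritParams rank_indications
#' @param n_iterations Expansion iterations per module.
#' @return A named list of disease [subnetwork]s keyed by `disease_id`.
#' @export
compute_disease_modules <- function(network, catalog, n_iterations = 200L) {
  setNames(
    map(catalog$seeds, function(s) {
      trace_subnetwork(diamond_expand(network, s, n_iterations))
    }),
    catalog$disease_id
  )
}

#' @export
tidy.indication_ranking <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "indication_ranking")
  out
}

#' @export
glance.indication_ranking <- function(x, ...) {
  tibble(
    n_ranked = nrow(x),
    n_significant_fdr = sum(x$fdr < 0.05),
    variant = attr(x, "variant") %||% NA_character_,
    top_metric = x$metric[1]
  )
}
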
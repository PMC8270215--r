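#' Area under the ROC curve of an indication ranking
#'
#' Probability that a uniformly chosen true indication outranks a uniformly
#' chosen non-indication, with rank ties counting one half. Equivalent to
#' the normalised Wilcoxon statistic of the rank-based ROC curve.
#'
#' @param ranking An indication ranking tibble with `rank` and `disease_id`
#'   columns (smaller rank = stronger prediction).
#' @param positives Character vector of disease ids that are true
#'   indications.
#' @return The AUROC in `[0, 1]`.
#' @export
auroc <- function(ranking, positives) {
  is_pos <- ranking$disease_id %in% positives
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) {
    abort("need at least one positive and one negative among ranked diseases")
  }
  # midranks of the "goodness" score (-rank) handle any ties
  r <- rank(-ranking$rank, ties.method = "average")
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Sensitivity within the top fraction of a ranking
#'
#' Fraction of the true indications found within the top
#' `ceiling(fraction * n_ranked)` ranks. The ceiling guarantees a non-empty
#' top slice for any positive fraction.
#'
#' @inheritParams auroc
#' @param fraction Threshold fraction in `(0, 1]`, e.g. `0.15` for "top
#'   15%%".
#' @return The sensitivity (recall) in `[0, 1]`.
#' @export
sensitivity_at_top <- function(ranking, positives, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  is_pos <- ranking$disease_id %in% positives
  if (sum(is_pos) == 0L || sum(!is_pos) == 0L) {
    abort("need at least one positive and one negative among ranked diseases")
  }
  cutoff <- ceiling(fraction * nrow(ranking))
  sum(is_pos & ranking$rank <= cutoff) / sum(is_pos)
}

#' Full evaluation report for a ranking
#'
#' Bundles the AUROC and the sensitivities at the standard top-rank
#' thresholds (5% to 30% in 5-point steps) against a ground-truth positive
#' set, optionally restricted to predictions with Holm-adjusted value below
#' `fdr_cutoff`.
#'
#' @inheritParams auroc
#' @param thresholds Top-rank fractions to evaluate.
#' @param fdr_cutoff Optional cutoff: when given and the ranking has an
#'   `fdr` column, a positive only counts as recovered at a threshold if
#'   its adjusted value is also below the cutoff.
#' @return An `evaluation_report` tibble with one row per threshold plus
#'   attributes `auroc`, `n_positives`, `n_ranked`.
#' @export
evaluate_ranking <- function(ranking, positives,
                             thresholds = seq(0.05, 0.30, by = 0.05),
                             fdr_cutoff = NULL) {
  auc <- auroc(ranking, positives)
  is_pos <- ranking$disease_id %in% positives
  apply_fdr <- !is.null(fdr_cutoff) && "fdr" %in% names(ranking)
  sens <- map_dbl(thresholds, function(f) {
    cutoff <- ceiling(f * nrow(ranking))
    hit <- is_pos & ranking$rank <= cutoff
    if (apply_fdr) hit <- hit & ranking$fdr < fdr_cutoff
    sum(hit) / sum(is_pos)
  })
  out <- tibble(threshold = thresholds, sensitivity = sens)
  class(out) <- c("evaluation_report", class(out))
  attr(out, "auroc") <- auc
  attr(out, "n_positives") <- sum(is_pos)
  attr(out, "n_ranked") <- nrow(ranking)
  out
}

#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(
    auroc = attr(x, "auroc"),
    n_positives = attr(x, "n_positives"),
    n_ranked = attr(x, "n_ranked")
  )
}

#' ROC curve coordinates of a ranking
#'
#' @inheritParams auroc
#' @return A tibble of `(fpr, tpr)` pairs tracing the rank-based ROC curve.
#' @export
roc_coordinates <- function(ranking, positives) {
  ord <- arrange(ranking, .data$rank)
  is_pos <- ord$disease_id %in% positives
  tibble(
    fpr = c(0, cumsum(!is_pos) / sum(!is_pos)),
    tpr = c(0, cumsum(is_pos) / sum(is_pos))
  )
}

#' Background performance of random targets
#'
#' Samples `n_targets` genes from a candidate pool (a druggable-gene list
#' when available, all network nodes otherwise), runs the full
#' indication-ranking workflow for each, and returns their AUROCs against
#' the same positive set. The mean is the chance-level performance a real
#' target must beat.
#'
#' @param network An [interaction_network].
#' @param catalog A `disease_catalog`.
#' @param positives Character vector of true-indication disease ids.
#' @param n_targets Number of random targets to draw (without
#'   replacement).
#' @param candidate_pool Character vector of candidate target genes;
#'   defaults to all network nodes.
#' @param seed Integer seed for the target draw.
#' @param config A [propagation_config()].
#' @param top_k,include_neighbors,variant,module_iterations,modules Passed
#'   to [build_target_subnetwork()] and [rank_indications()]; disease
#'   modules are computed once and shared across the random targets.
#' @return A tibble with columns `target` and `auroc`.
#' @export
random_target_background <- function(network, catalog, positives,
                                     n_targets = 100L,
                                     candidate_pool = NULL,
                                     seed = 1L,
                                     config = propagation_config(),
                                     top_k = 200L,
                                     include_neighbors = TRUE,
                                     variant = "plain",
                                     module_iterations = 200L,
                                     modules = NULL) {
  candidate_pool <- candidate_pool %||% network$nodes
  assert_in_network(network, candidate_pool, "candidate")
  if (length(candidate_pool) < n_targets) {
    abort("candidate pool smaller than the number of targets requested")
  }
  chosen <- withr::with_seed(
    seed, sample(candidate_pool, n_targets, replace = FALSE)
  )
  if (is.null(modules)) {
    modules <- compute_disease_modules(network, catalog, module_iterations)
  }
  aucs <- map_dbl(chosen, function(tg) {
    sub <- build_target_subnetwork(
      network, tg, config, top_k = top_k,
      include_neighbors = include_neighbors
    )
    rk <- rank_indications(
      network, sub, catalog, variant = variant,
      module_iterations = module_iterations, modules = modules
    )
    auroc(rk, positives)
  })
  tibble(target = chosen, auroc = aucs)
}
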
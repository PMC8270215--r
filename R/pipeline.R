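#' Configuration for an end-to-end indication-expansion run
#'
#' @param network_path Path to the interaction edge list.
#' @param disease_path Path to the gene-disease association table.
#' @param targets Character vector of target gene symbols.
#' @param truth_path Optional path to a TSV of (target, disease_id)
#'   ground-truth pairs; supplying it adds an evaluation report.
#' @param alpha,tolerance Propagation parameters
#'   ([propagation_config()]).
#' @param top_k Top propagation-ranked nodes kept in the target
#'   subnetwork.
#' @param module_iterations Disease-module expansion iterations.
#' @param variant `"plain"` or `"weighted"` enrichment.
#' @param score_threshold,score_scale Network confidence filter
#'   ([read_interactions()]).
#' @param min_seeds Minimum network seeds per retained disease.
#' @param shortlist_fraction Rankings within this top fraction are flagged
#'   in a `shortlisted` column (default 0.15, the recommended candidate
#'   shortlist cut).
#' @param out_dir Output directory.
#' @param seed Integer seed (recorded; the workflow itself is
#'   deterministic).
#' @param cache_dir Optional directory for on-disk disease-module caching
#'   across runs, keyed by a hash of (network edges, seeds, iterations).
#' @return A `run_config` list.
#' @export
run_config <- function(network_path, disease_path, targets,
                       truth_path = NULL,
                       alpha = 0.5, tolerance = 1e-6,
                       top_k = 200L, module_iterations = 200L,
                       variant = c("plain", "weighted"),
                       score_threshold = 0.7, score_scale = "auto",
                       min_seeds = 1L, shortlist_fraction = 0.15,
                       out_dir = tempfile("netindic_run_"),
                       seed = 1L, cache_dir = NULL) {
  variant <- match.arg(variant)
  for (p in c(network_path, disease_path, truth_path)) {
    if (!file.exists(p)) abort(paste0("input file not found: ", p))
  }
  structure(
    list(
      network_path = network_path, disease_path = disease_path,
      targets = as.character(targets), truth_path = truth_path,
      alpha = alpha, tolerance = tolerance, top_k = top_k,
      module_iterations = module_iterations, variant = variant,
      score_threshold = score_threshold, score_scale = score_scale,
      min_seeds = min_seeds, shortlist_fraction = shortlist_fraction,
      out_dir = out_dir, seed = seed, cache_dir = cache_dir
    ),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(
      paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
      parent = e
    )
  })
}

#' Run the indication-expansion workflow end to end
#'
#' Reads and filters the network, builds the target subnetwork by flow
#' propagation, grows every disease module, ranks all diseases by overlap
#' enrichment, and (when ground truth is supplied) evaluates the ranking.
#' Writes `ranking.tsv`, a `config.json` provenance snapshot, a
#' `run.log`, and `evaluation.json` when applicable, into
#' `config$out_dir`. The workflow is deterministic: identical
#' configuration and seed reproduce the output files byte for byte.
#'
#' @param config A [run_config()].
#' @return A list with elements `ranking` (an `indication_ranking`),
#'   `report` (an `evaluation_report` or `NULL`), and the output `paths`.
#' @export
run_expansion <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  net <- stage("graph_io", suppressMessages(read_interactions(
    config$network_path, config$score_threshold, config$score_scale
  )))
  note("network: ", length(net$nodes), " nodes, ", nrow(net$edges), " edges")
  catalog <- stage("graph_io", suppressMessages(read_disease_catalog(
    config$disease_path, net, config$min_seeds
  )))
  note("catalog: ", nrow(catalog), " diseases")

  pconf <- propagation_config(config$alpha, config$tolerance)
  target_sub <- stage("propagation", build_target_subnetwork(
    net, config$targets, pconf, top_k = config$top_k
  ))
  note("target subnetwork: ", length(target_sub$nodes), " nodes")

  modules <- stage("disease_module", cached_disease_modules(
    net, catalog, config$module_iterations, config$cache_dir
  ))
  ranking <- stage("enrichment", rank_indications(
    net, target_sub, catalog,
    variant = config$variant,
    module_iterations = config$module_iterations,
    modules = modules
  ))
  shortlist_n <- ceiling(config$shortlist_fraction * nrow(ranking))
  ranking <- mutate(ranking, shortlisted = .data$rank <= shortlist_n)
  note("ranking: ", nrow(ranking), " MeSH-deduplicated diseases, top ",
       shortlist_n, " shortlisted")

  report <- NULL
  if (!is.null(config$truth_path)) {
    truth <- readr::read_tsv(
      config$truth_path, show_col_types = FALSE, progress = FALSE
    )
    positives <- unique(truth$disease_id[
      truth$target %in% config$targets
    ])
    positives <- intersect(positives, ranking$disease_id)
    if (length(positives) > 0L && length(positives) < nrow(ranking)) {
      report <- stage("evaluation", evaluate_ranking(ranking, positives))
      note("evaluation: AUROC ", round(attr(report, "auroc"), 4),
           " over ", length(positives), " positive(s)")
    } else {
      note("evaluation skipped: ground truth leaves no positive/negative split")
    }
  }

  paths <- list(
    ranking = file.path(config$out_dir, "ranking.tsv"),
    config = file.path(config$out_dir, "config.json"),
    log = file.path(config$out_dir, "run.log")
  )
  readr::write_tsv(as_tibble(ranking), paths$ranking)
  jsonlite::write_json(
    unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    paths$config,
    auto_unbox = TRUE, pretty = TRUE
  )
  if (!is.null(report)) {
    paths$evaluation <- file.path(config$out_dir, "evaluation.json")
    jsonlite::write_json(
      c(as.list(glance(report)),
        list(sensitivity = as.list(setNames(
          report$sensitivity, paste0("top_", report$threshold * 100)
        )))),
      paths$evaluation,
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  writeLines(log_lines, paths$log)
  list(ranking = ranking, report = report, paths = paths)
}

# disk-backed memoisation of compute_disease_modules; equivalent to
# recomputation, keyed by content hashes
cached_disease_modules <- function(network, catalog, n_iterations,
                                   cache_dir = NULL) {
  if (is.null(cache_dir)) {
    return(compute_disease_modules(network, catalog, n_iterations))
  }
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  net_hash <- hash(network$edges)
  setNames(
    map(seq_len(nrow(catalog)), function(i) {
      seeds <- catalog$seeds[[i]]
      key <- hash(list(net_hash, sort(seeds), n_iterations))
      path <- file.path(cache_dir, paste0(key, ".tsv"))
      if (file.exists(path)) {
        cached <- readr::read_tsv(path, show_col_types = FALSE,
                                  progress = FALSE)
        subnetwork(cached$node, origin = cached$node[cached$is_origin],
                   construction = "disease")
      } else {
        sub <- trace_subnetwork(
          diamond_expand(network, seeds, n_iterations)
        )
        readr::write_tsv(tidy(sub), path)
        sub
      }
    }),
    catalog$disease_id
  )
}
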
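#' Read a confidence-filtered interaction network
#'
#' Reads a whitespace- or tab-delimited edge list in the STRING
#' protein-links dialect (two node columns, one combined-score column; an
#' optional header line is skipped automatically) and keeps only edges whose
#' confidence is strictly greater than `score_threshold`. Scores shipped on
#' the 0-1000 scale are normalised to fractions; by default the scale is
#' auto-detected (any score above 1 implies the 0-1000 scale). Nodes left
#' without a surviving edge are dropped, so every node of the returned
#' network has degree at least 1.
#'
#' @param path Path to the edge-list file.
#' @param score_threshold Confidence threshold as a fraction in `[0, 1]`;
#'   edges must exceed it strictly. Default `0.7`, the usual high-confidence
#'   cut for STRING networks.
#' @param score_scale `"auto"` (default), `"0-1"` or `"0-1000"`.
#' @return An [interaction_network]. The attribute `"io_report"` records rows
#'   read and edges kept.
#' @examples
#' f <- tempfile()
#' writeLines(c("A B 0.9", "B C 0.5", "A C 0.71"), f)
#' net <- read_interactions(f, score_threshold = 0.7)
#' network_edges(net)
#' @export
read_interactions <- function(path, score_threshold = 0.7,
                              score_scale = c("auto", "0-1", "0-1000")) {
  score_scale <- match.arg(score_scale)
  stopifnot(score_threshold >= 0, score_threshold <= 1)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort(paste0("no rows in ", path), class = "netindic_empty_network")
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    abort(
      paste0("malformed row at line ", bad[1], " of ", path,
             ": expected at least 3 whitespace-separated fields"),
      class = "netindic_malformed_row"
    )
  }
  first_score <- suppressWarnings(as.numeric(fields[[1]][3]))
  header_skipped <- FALSE
  if (is.na(first_score)) { # header line
    fields <- fields[-1]
    header_skipped <- TRUE
    if (length(fields) == 0L) {
      abort(paste0("no data rows in ", path), class = "netindic_empty_network")
    }
  }
  score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(score)) {
    line_no <- which(is.na(score))[1] + header_skipped
    abort(
      paste0("malformed row at line ", line_no, " of ", path,
             ": score is not numeric"),
      class = "netindic_malformed_row"
    )
  }
  if (score_scale == "auto") {
    score_scale <- if (any(score > 1)) "0-1000" else "0-1"
  }
  if (score_scale == "0-1000") score <- score / 1000
  edges <- tibble(
    from = vapply(fields, `[`, "", 1L),
    to = vapply(fields, `[`, "", 2L),
    weight = score
  )
  kept <- edges |> filter(.data$weight > score_threshold)
  if (nrow(kept) == 0L) {
    abort(
      paste0("no edges exceed threshold ", score_threshold, " in ", path),
      class = "netindic_empty_network"
    )
  }
  net <- interaction_network(kept)
  inform(paste0(
    "read_interactions: ", nrow(edges), " rows read, ",
    nrow(network_edges(net)), " unique edges kept (threshold ",
    score_threshold, "), ", length(network_nodes(net)), " nodes"
  ))
  attr(net, "io_report") <- tibble(
    rows_read = nrow(edges),
    edges_kept = nrow(network_edges(net)),
    nodes_kept = length(network_nodes(net))
  )
  net
}

#' Read a gene-disease association catalog
#'
#' Reads a DisGeNET-style tab-separated table with header columns
#' `geneSymbol`, `diseaseId`, `diseaseName`, `meshId` and `score` and builds
#' the per-disease seed-gene catalog used throughout the package. Seed sets
#' are intersected with the network's nodes; diseases without a MeSH
#' identifier, and diseases left with fewer than `min_seeds` seeds, are
#' dropped. No minimum association score is imposed: every listed gene
#' counts as a seed, with its score kept for the genetic baseline.
#'
#' @param path Path to the TSV file.
#' @param network An [interaction_network]; seed genes outside it are
#'   removed.
#' @param min_seeds Minimum surviving seeds for a disease to be retained.
#' @return A `disease_catalog`: a tibble with one row per retained disease
#'   and columns `disease_id`, `disease_name`, `mesh_id`, `n_seeds`, `seeds`
#'   (list of gene symbols) and `scores` (list of named association scores).
#'   The attribute `"drop_report"` counts entries dropped and why.
#' @export
read_disease_catalog <- function(path, network, min_seeds = 1L) {
  stopifnot(min_seeds >= 1)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("geneSymbol", "diseaseId", "diseaseName", "meshId", "score")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    abort(paste0(
      "disease table is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (any(tab$score < 0 | tab$score > 1, na.rm = TRUE)) {
    abort("association scores must lie in [0, 1]")
  }
  tab <- tab |>
    mutate(meshId = ifelse(
      is.na(.data$meshId) | !nzchar(trimws(.data$meshId)),
      NA_character_, as.character(.data$meshId)
    ))
  all_entries <- tab |>
    group_by(disease_id = as.character(.data$diseaseId)) |>
    summarise(
      disease_name = .data$diseaseName[1],
      mesh_id = .data$meshId[1],
      seeds = list(unique(.data$geneSymbol)),
      scores = list(setNames(.data$score, .data$geneSymbol)),
      .groups = "drop"
    )
  n_total <- nrow(all_entries)
  no_mesh <- is.na(all_entries$mesh_id)
  kept <- all_entries |>
    filter(!is.na(.data$mesh_id)) |>
    mutate(
      seeds = map(.data$seeds, intersect, network_nodes(network)),
      scores = map2(.data$scores, .data$seeds, ~ .x[intersect(names(.x), .y)]),
      n_seeds = lengths(.data$seeds)
    )
  too_few <- kept$n_seeds < min_seeds
  kept <- kept |>
    filter(.data$n_seeds >= min_seeds) |>
    select(
      "disease_id", "disease_name", "mesh_id", "n_seeds", "seeds", "scores"
    ) |>
    arrange(.data$disease_id)
  if (nrow(kept) == 0L) {
    abort("no diseases survive filtering", class = "netindic_empty_catalog")
  }
  inform(paste0(
    "read_disease_catalog: ", n_total, " diseases read, ",
    nrow(kept), " kept (", sum(no_mesh), " dropped for missing MeSH id, ",
    sum(too_few), " for < ", min_seeds, " network seeds)"
  ))
  new_disease_catalog(
    kept,
    drop_report = tibble(
      diseases_read = n_total,
      dropped_no_mesh = sum(no_mesh),
      dropped_few_seeds = sum(too_few),
      diseases_kept = nrow(kept)
    )
  )
}

new_disease_catalog <- function(df, drop_report = NULL) {
  out <- as_tibble(df)
  class(out) <- c("disease_catalog", class(out))
  attr(out, "drop_report") <- drop_report
  out
}

#' Construct a disease catalog from in-memory pieces
#'
#' Convenience constructor mirroring [read_disease_catalog()] for
#' programmatic use (simulations, tests).
#'
#' @param entries A data frame with columns `disease_id`, `disease_name`,
#'   `mesh_id`, `seeds` (list column) and `scores` (list column of named
#'   numeric vectors).
#' @return A `disease_catalog` tibble.
#' @export
disease_catalog <- function(entries) {
  entries <- as_tibble(entries) |>
    mutate(n_seeds = lengths(.data$seeds)) |>
    select(
      "disease_id", "disease_name", "mesh_id", "n_seeds", "seeds", "scores"
    ) |>
    arrange(.data$disease_id)
  stopifnot(all(entries$n_seeds >= 1))
  new_disease_catalog(entries)
}

#' Collapse an indication ranking to one entry per MeSH identifier
#'
#' DisGeNET-style catalogs list several disease terms under the same MeSH
#' identifier. To remove that redundancy from a final ranking, only the
#' best-ranked (smallest-rank) term per MeSH id is kept; survivors keep
#' their relative order, ranks are reassigned densely from 1, and the
#' inverse-rank association score is recomputed.
#'
#' @param ranking An indication ranking tibble with `rank` and `mesh_id`
#'   columns (as produced by [rank_indications()]).
#' @param catalog Optional `disease_catalog` supplying `mesh_id` when the
#'   ranking lacks the column.
#' @return The deduplicated ranking tibble.
#' @export
deduplicate_by_mesh <- function(ranking, catalog = NULL) {
  if (!"mesh_id" %in% names(ranking)) {
    if (is.null(catalog)) {
      abort("ranking lacks mesh_id and no catalog was supplied")
    }
    ranking <- ranking |>
      left_join(
        select(as_tibble(catalog), "disease_id", "mesh_id"),
        by = "disease_id"
      )
  }
  out <- ranking |>
    arrange(.data$rank) |>
    group_by(.data$mesh_id) |>
    slice(1L) |>
    ungroup() |>
    arrange(.data$rank) |>
    mutate(rank = row_number(), score = 1 / .data$rank)
  class(out) <- class(ranking)
  out
}
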
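#' Plot an indication ranking
#'
#' Metric (or z-score / association score, whichever the ranking carries)
#' against rank, with the shortlist fraction shaded and optional known
#' positives highlighted.
#'
#' @param object An `indication_ranking`.
#' @param positives Optional character vector of true-indication disease
#'   ids to highlight.
#' @param shortlist_fraction Top fraction to shade (default 0.15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.indication_ranking <- function(object, positives = NULL,
                                        shortlist_fraction = 0.15, ...) {
  ycol <- intersect(c("metric", "zscore", "assoc_score"), names(object))[1]
  df <- mutate(
    as_tibble(object),
    known = .data$disease_id %in% (positives %||% character(0))
  )
  cut <- ceiling(shortlist_fraction * nrow(df))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rank, y = .data[[ycol]], colour = .data$known
  )) +
    ggplot2::annotate(
      "rect", xmin = -Inf, xmax = cut + 0.5, ymin = -Inf, ymax = Inf,
      alpha = 0.08, fill = "steelblue"
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
      labels = c(`FALSE` = "other", `TRUE` = "known indication"),
      name = NULL
    ) +
    ggplot2::labs(
      x = "rank", y = ycol,
      title = "Indication ranking",
      subtitle = paste0("shaded: top ", 100 * shortlist_fraction,
                        "% shortlist")
    ) +
    ggplot2::theme_minimal()
  if (is.null(positives)) p <- p + ggplot2::guides(colour = "none")
  p
}

#' Plot an evaluation report
#'
#' Sensitivity against the top-rank threshold fraction, annotated with the
#' AUROC.
#'
#' @param object An `evaluation_report` from [evaluate_ranking()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(
    x = .data$threshold, y = .data$sensitivity
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "top-rank threshold", y = "sensitivity",
      title = "Recovery of known indications",
      subtitle = paste0("AUROC = ", round(attr(object, "auroc"), 3))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a module-expansion trace
#'
#' Connectivity p-value of each added node against its iteration index.
#'
#' @param object An `expansion_trace` from [diamond_expand()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.expansion_trace <- function(object, ...) {
  df <- filter(as_tibble(object), !.data$is_seed)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$iteration, y = -log10(.data$pvalue)
  )) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "expansion iteration", y = "-log10 connectivity p-value",
      title = "Disease-module growth"
    ) +
    ggplot2::theme_minimal()
}
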
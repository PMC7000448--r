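#' Tidy and glance methods
#'
#' broom-style accessors for the package's result objects: `tidy()`
#' returns the per-unit table (one row per flag, hit or node), and
#' `glance()` a one-row summary.
#'
#' @param x The result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(
    flag = x$flag, method = x$method,
    foreground_size = x$foreground_size, background_size = x$background_size,
    foreground_hits = x$foreground_hits, background_hits = x$background_hits,
    fraction_fg = x$fraction_fg, fraction_bg = x$fraction_bg,
    odds_ratio = x$odds_ratio, p_value = x$p_value, adjusted_p = x$adjusted_p
  )
}

#' @rdname tidiers
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    flag = x$flag, p_value = x$p_value,
    enriched = x$fraction_fg > x$fraction_bg
  )
}

#' @rdname tidiers
#' @method tidy cohort_classification
#' @export
tidy.cohort_classification <- function(x, ...) {
  dplyr::left_join(
    dplyr::select(
      x$hits, "patient_id", "gene", "categories", "n_variants",
      "zygosities", "inheritance_consistent", "consistency_reason", "tier"
    ),
    dplyr::select(x$classifications, "patient_id", "status"),
    by = "patient_id"
  )
}

#' @rdname tidiers
#' @method glance cohort_classification
#' @export
glance.cohort_classification <- function(x, ...) {
  counts <- dplyr::count(x$classifications, .data$status)
  wide <- tidyr::pivot_wider(counts,
    names_from = "status", values_from = "n", values_fill = 0L
  )
  missing <- setdiff(patient_statuses(), names(wide))
  for (m in missing) wide[[m]] <- 0L
  dplyr::mutate(wide[patient_statuses()],
    n_patients = x$n_patients,
    n_elevated_genes = nrow(x$elevated)
  )
}

#' @rdname tidiers
#' @method tidy connectivity_report
#' @export
tidy.connectivity_report <- function(x, ...) x$nodes

#' @rdname tidiers
#' @method glance connectivity_report
#' @export
glance.connectivity_report <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$nodes),
    n_edges = nrow(x$edges_used),
    n_components = x$n_components,
    fraction_with_candidate_neighbour = x$fraction_with_candidate_neighbour,
    ne_to_pm_path_exists = x$ne_to_pm_path_exists
  )
}

#' Plots for result objects
#'
#' `autoplot()` methods: classification status bars (coloured by
#' evidence tier at the hit level), enrichment fraction comparisons and
#' the induced candidate interaction graph.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplots
NULL

#' @rdname autoplots
#' @method autoplot cohort_classification
#' @export
autoplot.cohort_classification <- function(object, ...) {
  df <- dplyr::count(object$classifications, .data$status)
  df$status <- factor(df$status, levels = patient_statuses())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "patients") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname autoplots
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tibble(
    set = factor(c("foreground", "background"), c("foreground", "background")),
    fraction = c(object$fraction_fg, object$fraction_bg)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$fraction)) +
    ggplot2::geom_col(fill = c("steelblue", "grey60")) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(
      title = object$flag,
      subtitle = sprintf("one-sided %s p = %.3g", object$method, object$p_value),
      x = NULL, y = "flagged fraction"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplots
#' @method autoplot connectivity_report
#' @export
autoplot.connectivity_report <- function(object, ...) {
  g <- igraph::graph_from_data_frame(
    object$edges_used[, c("gene_a", "gene_b")],
    directed = FALSE,
    vertices = data.frame(name = object$nodes$gene)
  )
  layout <- withr::with_seed(1L, igraph::layout_with_fr(g))
  nodes <- dplyr::mutate(object$nodes,
    x = layout[, 1], y = layout[, 2],
    localisation = dplyr::case_when(
      .data$ne ~ "nuclear envelope",
      .data$pm ~ "plasma membrane",
      TRUE ~ "other"
    )
  )
  seg <- dplyr::mutate(object$edges_used,
    x = nodes$x[match(.data$gene_a, nodes$gene)],
    y = nodes$y[match(.data$gene_a, nodes$gene)],
    xend = nodes$x[match(.data$gene_b, nodes$gene)],
    yend = nodes$y[match(.data$gene_b, nodes$gene)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      colour = "grey70"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$localisation),
      size = 3
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$gene),
      vjust = -1, size = 3
    ) +
    ggplot2::scale_colour_manual(values = c(
      "nuclear envelope" = "#1b9e77", "plasma membrane" = "#d95f02",
      "other" = "grey40"
    )) +
    ggplot2::theme_void()
}
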
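#' Miami plot of association results
#'
#' Signed -log10 p-values by exposure family, coloured by molecular
#' layer.
#'
#' @param records Association records (or a precomputed [miami_table()]).
#' @param period Optional period filter.
#' @param seed Jitter seed.
#' @return A ggplot object.
#' @export
plot_miami <- function(records, period = NULL, seed = 1) {
  tab <- if ("signed_log10p" %in% names(records)) {
    records
  } else {
    miami_table(records, period, seed)
  }
  ggplot2::ggplot(
    tab,
    ggplot2::aes(
      x = .data$x, y = .data$signed_log10p, colour = .data$layer
    )
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_x_continuous(
      breaks = seq_along(sort(unique(tab$family))),
      labels = sort(unique(tab$family))
    ) +
    ggplot2::labs(
      x = "exposure family",
      y = expression(sign(beta) %*% -log[10](p)),
      colour = "layer"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Forest plot of a meta-analysed association
#'
#' Cohort point estimates with confidence intervals and the pooled
#' fixed/random rows.
#'
#' @param forest A [forest_table()] (rows of one association).
#' @return A ggplot object.
#' @export
plot_forest <- function(forest) {
  forest$label <- factor(forest$label, levels = rev(unique(forest$label)))
  ggplot2::ggplot(
    forest,
    ggplot2::aes(x = .data$estimate, y = .data$label, shape = .data$row_type)
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(
      values = c(cohort = 15, fixed = 18, random = 5)
    ) +
    ggplot2::labs(x = "effect (per IQR)", y = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for association tables: Miami plot
#'
#' @param object An `exwas_tbl`.
#' @param ... Passed to [plot_miami()].
#' @return A ggplot object.
#' @method autoplot exwas_tbl
#' @export
autoplot.exwas_tbl <- function(object, ...) {
  plot_miami(object, ...)
}

#' Autoplot method for association networks
#'
#' Deterministic force-directed layout with exposures as squares and
#' features as circles, coloured by layer.
#'
#' @param object An `assoc_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot assoc_network
#' @export
autoplot.assoc_network <- function(object, seed = 1, ...) {
  xy <- with_preserved_seed(
    seed, igraph::layout_with_fr(object$graph)
  )
  nodes <- mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    left_join(select(nodes, "name", x_from = "x", y_from = "y"),
      by = c(exposure = "name")
    ) |>
    left_join(select(nodes, "name", x_to = "x", y_to = "y"),
      by = c(feature = "name")
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$x_from, y = .data$y_from,
        xend = .data$x_to, yend = .data$y_to,
        colour = factor(.data$sign)
      ),
      linewidth = 0.3, alpha = 0.6
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(
        x = .data$x, y = .data$y,
        fill = .data$layer, shape = .data$type
      ),
      size = 2
    ) +
    ggplot2::scale_shape_manual(values = c(exposure = 22, feature = 21)) +
    ggplot2::scale_colour_manual(
      values = c(`-1` = "#b2182b", `1` = "#2166ac"),
      labels = c(`-1` = "negative", `1` = "positive"),
      name = "association"
    ) +
    ggplot2::theme_void()
}
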
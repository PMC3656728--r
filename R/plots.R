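#' Plot eigentrait variance fractions and loadings
#'
#' Two-panel style summary of a decomposition: the variance fraction per
#' eigentrait and the phenotype loadings of the retained eigentraits.
#'
#' @param object An `eigentrait_decomposition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eigentrait_decomposition <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(
    td,
    ggplot2::aes(
      x = .data$phenotype, y = .data$loading,
      fill = factor(.data$eigentrait)
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~eigentrait,
      labeller = ggplot2::as_labeller(function(j) {
        sprintf(
          "ET%s (%.1f%% variance)", j,
          100 * object$var_frac[as.integer(j)]
        )
      })
    ) +
    ggplot2::labs(
      x = NULL, y = "phenotype loading",
      title = "Eigentrait composition"
    ) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of directed influences
#'
#' Influence coefficient against adjusted significance, one point per
#' direction per estimable pair.
#'
#' @param object A `kd_significance` from [adjust_significance()].
#' @param cutoff Adjusted-p cutoff drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kd_significance <- function(object, cutoff = 0.01, ...) {
  infl <- object$influences
  long <- dplyr::bind_rows(
    tibble::tibble(m = infl$m_ab, adj_p = infl$adj_p_ab, direction = "a to b"),
    tibble::tibble(m = infl$m_ba, adj_p = infl$adj_p_ba, direction = "b to a")
  )
  long <- long[is.finite(long$m) & is.finite(long$adj_p), , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$m, y = -log10(.data$adj_p),
    colour = .data$adj_p < cutoff
  )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(cutoff), linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#c03030", `FALSE` = "grey60"),
      guide = "none"
    ) +
    ggplot2::labs(
      x = "directed influence m", y = "-log10 adjusted p",
      title = "Knockdown-to-knockdown influences"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an influence network
#'
#' Gene and phenotype nodes on a force-directed layout; green edges are
#' enhancing (positive influence), red edges suppressive (negative).
#'
#' @param object An `influence_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.influence_network <- function(object, seed = 1, ...) {
  g <- as_igraph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, weights = NA) # signed m is not a distance
  nodes <- tibble::tibble(
    name = igraph::V(g)$name, type = igraph::V(g)$type,
    x = xy[, 1], y = xy[, 2]
  )
  el <- igraph::as_data_frame(g, what = "edges")
  if (nrow(el)) {
    el <- dplyr::left_join(el, nodes[, c("name", "x", "y")], by = c(from = "name"))
    el <- dplyr::left_join(el, nodes[, c("name", "x", "y")],
      by = c(to = "name"), suffix = c("", "_to")
    )
  }
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(el)) {
    p <- p + ggplot2::geom_segment(
      data = el,
      ggplot2::aes(
        xend = .data$x_to, yend = .data$y_to,
        colour = factor(sign(.data$weight)),
        linewidth = abs(.data$weight)
      ),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      alpha = 0.7
    )
  }
  p +
    ggplot2::geom_point(ggplot2::aes(shape = .data$type), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), vjust = -1, size = 3) +
    ggplot2::scale_colour_manual(
      values = c(`-1` = "#c03030", `1` = "#2f8f2f"),
      labels = c(`-1` = "suppressive", `1` = "enhancing"),
      name = NULL
    ) +
    ggplot2::scale_linewidth(range = c(0.3, 1.5), guide = "none") +
    ggplot2::labs(title = sprintf("Influence network (adjusted p < %g)", object$cutoff)) +
    ggplot2::theme_void()
}

#' Single-scan statistic profile with the familywise threshold
#'
#' @param scan Tibble from [single_locus_scan()].
#' @param null Optional `kd_scan_null`; when given, the EVD threshold at
#'   `alpha` is drawn.
#' @param alpha Level for the threshold line.
#' @return A ggplot object.
#' @export
plot_single_scan <- function(scan, null = NULL, alpha = 0.001) {
  p <- ggplot2::ggplot(
    scan,
    ggplot2::aes(
      x = .data$gene, y = abs(.data$stat),
      fill = factor(.data$eigentrait)
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "|test statistic|", fill = "eigentrait",
      title = "Single-locus scan"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  if (!is.null(null)) {
    p <- p + ggplot2::geom_hline(
      yintercept = evd_threshold(null, alpha),
      linetype = 2, colour = "#c03030"
    )
  }
  p
}
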
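#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_tile geom_errorbar labs facet_wrap scale_fill_gradient2
#'   theme_minimal
#' @export
ggplot2::autoplot

#' Plot an elbow curve
#'
#' Mean cosine distance against k, with the chosen elbow highlighted.
#'
#' @param object An [elbow_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.elbow_curve <- function(object, ...) {
  k_star <- elbow_select(object)
  ggplot(object, aes(x = .data$k, y = .data$mean_distance)) +
    geom_line(color = "grey40") +
    geom_point(aes(color = .data$k == k_star), size = 2, show.legend = FALSE) +
    ggplot2::scale_color_manual(values = c("FALSE" = "grey30", "TRUE" = "red")) +
    labs(
      x = "k", y = "mean cosine distance",
      title = sprintf("Elbow criterion (chosen k = %d)", k_star)
    ) +
    theme_minimal()
}

#' Plot the reliability histogram of the chosen k
#'
#' @param object A [bootstrap_k()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.k_reliability <- function(object, ...) {
  ggplot(tidy(object), aes(x = factor(.data$k), y = .data$count)) +
    geom_col(fill = "steelblue") +
    labs(
      x = "chosen k", y = "resamples",
      title = sprintf("Elbow choice across %d half samples", object$n_resamples)
    ) +
    theme_minimal()
}

#' Centroid heatmaps of a cosine k-means fit
#'
#' Reconstructs each centroid's ROI x ROI Fisher-z matrix and displays it
#' with ROIs ordered by network, so the within/between-network block
#' structure is visible.
#'
#' @param object A [cosine_kmeans()] fit on full-resolution FC vectors.
#' @param atlas Atlas partition matching the FC dimensionality.
#' @param ... Unused.
#' @return A ggplot, faceted by cluster.
#' @export
autoplot.cosine_kmeans <- function(object, atlas = default_atlas(), ...) {
  n_rois <- nrow(atlas)
  validate_atlas(atlas)
  ord <- order(atlas$network, atlas$roi_index)
  idx <- connection_index(n_rois)
  dfs <- lapply(seq_len(object$k), function(cl) {
    m <- matrix(0, n_rois, n_rois)
    m[lower.tri(m)] <- object$centroids[cl, ]
    m <- m + t(m)
    m <- m[ord, ord]
    tibble::tibble(
      cluster = paste("cluster", cl),
      row = rep(seq_len(n_rois), n_rois),
      col = rep(seq_len(n_rois), each = n_rois),
      z = as.vector(m)
    )
  })
  ggplot(dplyr::bind_rows(dfs), aes(.data$col, .data$row, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    facet_wrap(~cluster) +
    labs(
      x = "ROI (network order)", y = "ROI (network order)",
      fill = "Fisher z",
      title = "Cluster centroids"
    ) +
    theme_minimal()
}

#' Design/behavior saliences of a PLS pattern with bootstrap intervals
#'
#' @param object An `fc_pls` fit; intervals require [pls_bootstrap()].
#' @param pattern Pattern number (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fc_pls <- function(object, pattern = 1, ...) {
  sal <- tibble::tibble(
    design = rownames(object$design_salience),
    salience = object$design_salience[, pattern]
  )
  p <- ggplot(sal, aes(x = .data$design, y = .data$salience)) +
    geom_col(fill = "steelblue") +
    labs(
      x = NULL, y = "salience",
      title = sprintf(
        "%s PLS, pattern %d (%.1f%% of covariance)",
        object$type, pattern,
        100 * object$patterns$covariance_fraction[pattern]
      )
    ) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(object$design_salience_ci)) {
    ci <- dplyr::filter(object$design_salience_ci, .data$pattern == !!pattern)
    p <- p + geom_errorbar(
      data = ci,
      aes(x = .data$design, y = .data$salience, ymin = .data$lo, ymax = .data$hi),
      width = 0.2
    )
  }
  p
}

#' Tile plot of network-pair contributions
#'
#' @param object An [block_contributions()] result.
#' @param ... Unused.
#' @return A ggplot with positive and negative panels.
#' @export
autoplot.rsn_contributions <- function(object, ...) {
  long <- tidyr::pivot_longer(object$table, c("positive", "negative"),
    names_to = "sign", values_to = "contribution"
  ) |>
    tidyr::separate_wider_delim("pair", "|", names = c("net_a", "net_b"))
  ggplot(long, aes(.data$net_a, .data$net_b, fill = .data$contribution)) +
    geom_tile() +
    scale_fill_gradient2(low = "darkgreen", mid = "white", high = "darkorange") +
    facet_wrap(~sign) +
    labs(x = NULL, y = NULL, title = "Network-pair contributions") +
    theme_minimal()
}

#' Brain-score versus behavior-score scatter for a behavior PLS pattern
#'
#' @param fit A behavior `fc_pls` fit.
#' @param pattern Pattern number (default 1).
#' @param color Optional vector (aligned with the complete-case subjects)
#'   used to color points, e.g. diagnosis.
#' @return A ggplot.
#' @export
plot_score_scatter <- function(fit, pattern = 1, color = NULL) {
  if (fit$type != "behavior") abort("score scatter needs a behavior PLS fit")
  df <- tibble::tibble(
    brain = fit$brain_scores[, pattern],
    behavior = fit$behavior_scores[, pattern],
    group = fit$groups
  )
  if (!is.null(color)) df$color <- color
  ggplot(df, aes(.data$brain, .data$behavior,
    color = if (is.null(color)) .data$group else .data$color
  )) +
    geom_point(alpha = 0.7) +
    labs(
      x = "brain score", y = "behavior score", color = NULL,
      title = sprintf("Behavior PLS pattern %d", pattern)
    ) +
    theme_minimal()
}
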
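#' Ordination scatter plot
#'
#' @param object A [pcoa_ord()] result.
#' @param metadata Optional per-sample metadata (`sample` + variables).
#' @param colour Optional metadata column to colour points by.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.toxbiome_pcoa <- function(object, metadata = NULL, colour = NULL,
                                   ...) {
  df <- object$coordinates
  if (!is.null(metadata)) {
    df <- dplyr::left_join(df, as_tibble(metadata), by = "sample")
  }
  lab <- function(i) {
    sprintf("Axis %d (%.1f%%)", i, 100 * object$prop_explained[i])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2))
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = lab(1), y = lab(2)) + ggplot2::theme_minimal()
}

#' Bar plot of PERMANOVA effect sizes
#'
#' @param object A [permanova()] result.
#' @param ... Ignored.
#' @return A ggplot of per-term R^2, annotated with permutation p-values.
#' @export
autoplot.toxbiome_permanova <- function(object, ...) {
  df <- object[!object$term %in% c("Residual", "Total"), ]
  df$term <- stats::reorder(df$term, df$r_squared)
  ggplot2::ggplot(df, ggplot2::aes(.data$term, .data$r_squared)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("p=%.3f", .data$p_value)), hjust = -0.1, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(R^2)) +
    ggplot2::theme_minimal()
}

#' Alpha diversity over time by group
#'
#' @param alpha Tibble from [alpha_diversity()].
#' @param samples Per-sample metadata with `sample`, `timepoint`, and the
#'   grouping column.
#' @param metric Which diversity column to plot.
#' @param group Grouping column name (default `"hti_group"`).
#' @return A ggplot box plot of diversity per time point, split by group.
#' @export
plot_alpha_diversity <- function(alpha, samples, metric = "shannon",
                                 group = "hti_group") {
  df <- dplyr::inner_join(alpha, as_tibble(samples), by = "sample")
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$timepoint),
                                   .data[[metric]],
                                   fill = .data[[group]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "Time point", y = metric) +
    ggplot2::theme_minimal()
}

#' MR scatter plot with fitted causal-effect lines
#'
#' @param h A [harmonize_gwas()] result.
#' @param results Optional [mr_estimate()] result; fitted slopes are drawn
#'   through the origin (Egger with its intercept).
#' @return A ggplot of outcome vs exposure effects with error bars.
#' @export
plot_mr <- function(h, results = NULL) {
  df <- as_tibble(h[h$retained, ])
  s <- sign(df$beta_exposure); s[s == 0] <- 1
  df$bx <- df$beta_exposure * s
  df$by <- df$beta_outcome * s
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$bx, .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$by - 1.96 * .data$se_outcome,
      ymax = .data$by + 1.96 * .data$se_outcome),
      width = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SNP effect on exposure",
                  y = "SNP effect on outcome") +
    ggplot2::theme_minimal()
  if (!is.null(results)) {
    ab <- tibble(method = results$method, slope = results$estimate,
                 intercept = 0)
    p <- p + ggplot2::geom_abline(
      data = ab, ggplot2::aes(slope = .data$slope,
                              intercept = .data$intercept,
                              colour = .data$method))
  }
  p
}

#' Driver-score lollipop plot
#'
#' @param drivers A [driver_scores()] result.
#' @param top Number of taxa to show.
#' @return A ggplot of the top combined driver scores.
#' @export
plot_drivers <- function(drivers, top = 15) {
  df <- utils::head(drivers, top)
  df$taxon <- stats::reorder(df$taxon, df$driver_score)
  ggplot2::ggplot(df, ggplot2::aes(.data$driver_score, .data$taxon)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$driver_score,
                                       yend = .data$taxon),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$driver), size = 2) +
    ggplot2::labs(x = "Driver score", y = NULL) +
    ggplot2::theme_minimal()
}
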
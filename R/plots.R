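#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot predictive gaze curves
#'
#' Looking probability (or gaze weight / expected weight) per area as the
#' swept trait moves across the 1-7 scale.
#'
#' @param object A [predict_gaze_curve()] result.
#' @param which `"probability"`, `"gaze_weight"` or `"expected_weight"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gaze_curve <- function(object, which = c("probability",
                                                  "gaze_weight",
                                                  "expected_weight"), ...) {
  which <- match.arg(which)
  lab <- c(probability = "P(area looked at)",
           gaze_weight = "gaze weight given looking (beta mean)",
           expected_weight = "expected gaze weight")[[which]]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data[[which]],
                                       colour = .data$area)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_continuous(breaks = 1:7) +
    ggplot2::labs(x = sprintf("%s score", toupper(object$trait[1])),
                  y = lab, colour = "area") +
    ggplot2::theme_minimal()
}

#' Plot predictive rating curves
#'
#' Expected rating across the swept trait, with the category probabilities
#' as shaded bands.
#'
#' @param object A [predict_rating_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rating_curve <- function(object, ...) {
  expected <- dplyr::distinct(object, .data$value, .data$expected)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$probability,
                                   fill = factor(.data$category)),
                      position = "stack", width = 0.2, alpha = 0.7) +
    ggplot2::geom_line(data = expected,
                       ggplot2::aes(y = .data$expected / 7),
                       linewidth = 1) +
    ggplot2::scale_y_continuous(
      name = "category probability (stacked)",
      sec.axis = ggplot2::sec_axis(~ . * 7, name = "expected rating")) +
    ggplot2::scale_x_continuous(breaks = 1:7) +
    ggplot2::labs(x = sprintf("%s score", toupper(object$trait[1])),
                  fill = "rating") +
    ggplot2::theme_minimal()
}

#' Posterior interval plot of a fit
#'
#' Posterior means and 95% HDIs of the fixed effects (for condition fits,
#' the pairwise contrasts against the reference), in the style of
#' forest-type contrast figures: effects whose HDI excludes 0 are
#' highlighted.
#'
#' @param object An `impress_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.impress_fit <- function(object, ...) {
  df <- tidy(object) %>% filter(.data$class == "fixed")
  df$label <- ifelse(is.na(df$area), df$term,
                     paste0(df$block, ".", df$area, ".", df$predictor))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$label,
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "posterior mean and 95% HDI", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a gaze weight map
#'
#' @param map A [gaze_weight_map()] matrix.
#' @param mask_set Optional [sim_masks()] mask set whose area outlines are
#'   overlaid.
#' @return A ggplot.
#' @export
plot_weight_map <- function(map, mask_set = NULL) {
  df <- tidyr::expand_grid(y = seq_len(nrow(map)), x = seq_len(ncol(map)))
  df$w <- as.vector(t(map))
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                         fill = .data$w)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "weight") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
  if (!is.null(mask_set)) {
    edge <- which(mask_set$labels > 0, arr.ind = TRUE)
    gg <- gg + ggplot2::annotate("point", x = edge[, 2], y = edge[, 1],
                                 size = 0.01, alpha = 0.05, colour = "white")
  }
  gg
}
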
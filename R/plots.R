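#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

img_to_df <- function(px) {
  H <- dim(px)[1]; W <- dim(px)[2]
  tibble::tibble(
    row = rep(seq_len(H), W), col = rep(seq_len(W), each = H),
    value = as.numeric(px))
}

#' Plot a heatmap
#'
#' @param object A [heatmap()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.heatmap <- function(object, ...) {
  df <- img_to_df(array(object$values, c(dim(object$values), 1L)))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "difference") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s heatmap%s%s", toupper(object$method),
                                  if (object$flags$ycbcr_applied) " +YCbCr" else "",
                                  if (object$flags$erosion_applied) " +erosion" else ""),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an image grid
#'
#' @param object An [image_grid()].
#' @param ... Unused.
#' @return A ggplot (RGB raster).
#' @export
autoplot.image_grid <- function(object, ...) {
  u <- convert_range(object, "unit")$pixels
  H <- dim(u)[1]; W <- dim(u)[2]
  cols <- if (dim(u)[3] == 3)
    grDevices::rgb(u[, , 1], u[, , 2], u[, , 3]) else
    grDevices::gray(u[, , 1])
  df <- tibble::tibble(row = rep(seq_len(H), W),
                       col = rep(seq_len(W), each = H), fill = cols)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot inversion / adaptation loss traces
#'
#' @param object A `latent_state`.
#' @param ... Unused.
#' @return A ggplot of the image loss over iterations (log scale).
#' @export
autoplot.latent_state <- function(object, ...) {
  ggplot2::ggplot(object$loss_trace,
                  ggplot2::aes(.data$iteration, .data$image_loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "perceptual loss",
                  title = "Inversion image loss") +
    ggplot2::theme_minimal()
}

#' Plot an ablation grid
#'
#' @param object An `ablation_result`.
#' @param ... Unused.
#' @return A ggplot tile grid of Pearson r by method, variant, mask and arm.
#' @export
autoplot.ablation_result <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(.data$variant, .data$method, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", 100 * .data$r)),
                       size = 3) +
    ggplot2::facet_grid(arm ~ mask_kind) +
    ggplot2::scale_fill_viridis_c(limits = c(-1, 1), name = "Pearson r") +
    ggplot2::labs(x = "processing", y = "heatmap method") +
    ggplot2::theme_minimal()
}

#' Machine-vs-human score scatter
#'
#' @param scores Tibble with `image_id` and `score`.
#' @param ratings A [rating_table()].
#' @param min_ratings Minimum ratings per image.
#' @return A ggplot with the fitted line and Pearson r annotation.
#' @export
plot_score_agreement <- function(scores, ratings, min_ratings = 20) {
  ev <- evaluate_scores(scores, ratings, min_ratings)
  ggplot2::ggplot(ev$data, ggplot2::aes(.data$mean_rating, .data$score)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "mean human rating (1-7)", y = "machine score S",
                  title = sprintf("machine-human agreement: r = %.3f (n = %d)",
                                  ev$r, ev$n)) +
    ggplot2::theme_minimal()
}
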
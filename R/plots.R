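#' Plot group means with 95% confidence intervals
#'
#' Figure-style summary of a comparison: one point per group mean with its
#' 95% CI error bar.
#'
#' @param object A `group_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.group_comparison <- function(object, ...) {
  gs <- object$group_stats
  ggplot2::ggplot(gs, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper), width = 0.15) +
    ggplot2::labs(
      y = "mean (95% CI)", x = NULL,
      subtitle = sprintf("%s: p = %.3g", object$route_taken, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot Sholl profiles
#'
#' @param cells Tibble from [measure_cells()] (with the nested `sholl` list
#'   column), or a single profile tibble from [sholl_profile()].
#' @param colour_by Column used to colour per-cell curves (default
#'   `class_label` when present).
#' @return A ggplot of intersections against shell radius.
#' @export
plot_sholl <- function(cells, colour_by = "class_label") {
  if (!is.null(cells$radius_um)) {
    df <- dplyr::mutate(cells, cell_id = 1L, group = "cell")
  } else {
    df <- tidyr::unnest(
      dplyr::select(cells, "cell_id",
                    dplyr::any_of(colour_by), "sholl"),
      "sholl")
    df$group <- if (colour_by %in% names(df)) df[[colour_by]] else "cell"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radius_um, y = .data$intersections,
                                   group = .data$cell_id,
                                   colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "shell radius (µm)", y = "intersections",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Display a maximum projection of a stack
#'
#' @param stack An [image_stack()].
#' @param role Channel to display (default first channel).
#' @return A ggplot raster of the max projection.
#' @export
plot_projection <- function(stack, role = stack$channel_roles[1]) {
  proj <- project_stack(stack, "max")
  img <- get_channel(proj, role)[1, , ]
  df <- expand.grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  df$intensity <- as.vector(img)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = role, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
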
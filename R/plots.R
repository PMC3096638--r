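#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the package's objects:
#' curves (optionally several overlaid via [plot_curves()]), BFS point
#' clouds, efficiency profiles, accuracy matrices, and evaluation reports.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name netcurve-plots
NULL

#' @rdname netcurve-plots
#' @export
autoplot.bfs_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "queue position / N", y = "parent position / N",
      title = sprintf(
        "%s curve (%s)", attr(object, "kind"), attr(object, "provenance")
      )
    )
}

#' Overlay several characteristic curves
#'
#' @param ... Named `bfs_curve` objects.
#' @param rescale Divide each curve's axes by its alignment scale so curves
#'   of different average degree are comparable.
#' @return A ggplot object.
#' @export
plot_curves <- function(..., rescale = TRUE) {
  curves <- list(...)
  if (is.null(names(curves)) || any(names(curves) == "")) {
    names(curves) <- paste0("curve", seq_along(curves))
  }
  df <- bind_rows(lapply(names(curves), function(nm) {
    cur <- curves[[nm]]
    sc <- if (rescale) curve_scale(cur) else 1
    tibble(curve = nm, x = cur$x / sc, y = cur$y / sc)
  }))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$x, y = .data$y, colour = .data$curve
  )) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "x", y = "f(x)")
}

#' @rdname netcurve-plots
#' @export
autoplot.bfs_mapping <- function(object, ...) {
  df <- bind_rows(
    mutate(object$tree_points[, c("x", "y")], cloud = "BFS-tree"),
    mutate(object$graph_points, cloud = "BFS-graph")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::facet_wrap(~cloud, scales = "free") +
    ggplot2::labs(x = "queue position / N", y = "parent position / N")
}

#' @rdname netcurve-plots
#' @export
autoplot.efficiency_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("x", "d_graph", "d_tree", "eta")],
    -"x",
    names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "queue position / N")
}

#' @rdname netcurve-plots
#' @export
autoplot.accuracy_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$predicted, y = .data$true, fill = .data$percent
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$percent))) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "classified as", y = "generated by", fill = "%")
}

#' @rdname netcurve-plots
#' @export
autoplot.evaluation_report <- function(object, ...) {
  ggplot2::ggplot(object$distances, ggplot2::aes(
    x = .data$model, y = .data$distance
  )) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "curve distance to target")
}
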
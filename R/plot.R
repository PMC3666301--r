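#' Plot a vectorised image as a ggplot raster
#'
#' @param values Numeric or logical vector of length `prod(shape)`, or a
#'   matrix/array.
#' @param shape Image extents; inferred when `values` has dimensions.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_image <- function(values, shape = NULL, title = NULL) {
  if (!is.null(dim(values))) {
    shape <- dim(values)
    values <- as.vector(values)
  }
  if (is.null(shape)) stop("`shape` is required for vector input")
  if (length(values) != prod(shape))
    stop("`values` length does not match `shape`")
  df <- tibble::tibble(
    x = rep(seq_len(shape[1L]), times = shape[2L]),
    y = rep(seq_len(shape[2L]), each = shape[1L]),
    value = as.numeric(values)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_image
#' @param object A `probability_image`.
#' @param which `"frequency"` or `"binary"`.
#' @param ... Unused.
#' @method autoplot probability_image
#' @export
autoplot.probability_image <- function(object, shape,
                                       which = c("frequency", "binary"),
                                       ...) {
  which <- match.arg(which)
  vals <- if (which == "binary") as.numeric(object$binary) else
    object$frequency
  plot_image(vals, shape = shape,
             title = paste0("selection ", which, " (",
                            object$n_replicates, " replicates)"))
}

#' Heatmap of a Q-squared grid search
#'
#' One tile per penalty pair, faceted by the number of components; the
#' selected cell maximises Q-squared.
#'
#' @param object A [grid_search()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot q2_grid
#' @export
autoplot.q2_grid <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(signif(.data$lamX, 3)),
                                    y = factor(signif(.data$lamY, 3)),
                                    fill = .data$Q2)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = expression(lambda[X]), y = expression(lambda[Y])) +
    ggplot2::theme_minimal()
}

#' Dot plot of simulation-study selection metrics
#'
#' @param object A [run_simulation_study()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sim_study
#' @export
autoplot.sim_study <- function(object, ...) {
  long <- tidyr_pivot(object$metrics)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value,
                                     colour = factor(.data$component))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, colour = "component") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

# minimal long-format reshape of the metrics table (avoids a tidyr
# dependency for one call)
tidyr_pivot <- function(metrics) {
  cols <- c("sensitivity", "specificity", "c_index")
  dplyr::bind_rows(lapply(cols, function(cn)
    tibble::tibble(method = metrics$method, component = metrics$component,
                   metric = cn, value = metrics[[cn]])))
}
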
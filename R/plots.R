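# ggplot2 methods for the package's result types.

#' @importFrom ggplot2 ggplot aes geom_raster geom_point geom_line geom_tile
#'   scale_fill_viridis_c scale_colour_viridis_c coord_equal labs theme_minimal
#'   facet_wrap autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot the region labels of a labeled mesh
#'
#' @param object A `labeled_mesh`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.labeled_mesh <- function(object, ...) {
  ggplot(object$nodes, aes(.data$x, .data$y, fill = .data$region)) +
    geom_raster() +
    coord_equal() +
    labs(x = "x (mm)", y = "y (mm)", fill = NULL) +
    theme_minimal()
}

#' Plot a marker map
#'
#' Activation (or repolarization) times per electrode, one panel per beat.
#'
#' @param object A `marker_map` that carries electrode positions via the
#'   accompanying `grid` argument, or a node-indexed field map plus `mesh`.
#' @param grid Optional `recording_grid` giving electrode positions.
#' @param mesh Optional `labeled_mesh` when `object` is node-indexed.
#' @param value `"at"` or `"rt"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.marker_map <- function(object, grid = NULL, mesh = NULL,
                                value = c("at", "rt"), ...) {
  value <- match.arg(value)
  df <- as_tibble(object)
  if (!is.null(grid)) {
    pos <- grid[match(df$electrode, grid$electrode), c("x", "y")]
    df$x <- pos$x; df$y <- pos$y
  } else if (!is.null(mesh)) {
    df$x <- mesh$nodes$x[df$electrode]
    df$y <- mesh$nodes$y[df$electrode]
  } else abort("supply `grid` or `mesh` for electrode positions")
  ggplot(df, aes(.data$x, .data$y, colour = .data[[value]])) +
    geom_point(size = 0.8) +
    scale_colour_viridis_c() +
    coord_equal() +
    facet_wrap(~beat) +
    labs(x = "x (mm)", y = "y (mm)",
         colour = sprintf("%s (ms)", toupper(value))) +
    theme_minimal()
}

#' Plot an RVI map
#'
#' Node-indexed maps render as a raster, electrode-indexed maps as points.
#' Values are capped at `cap` to keep the vulnerable region visible against
#' the physiological background.
#'
#' @param object An `rvi_map`.
#' @param cap Upper display cap, ms (default 250).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rvi_map <- function(object, cap = 250, ...) {
  df <- as_tibble(object)
  df$rvi_disp <- pmin(df$rvi, cap)
  ttl <- sprintf("RVI map: %s, R = %g mm",
                 attr(object, "method"), attr(object, "radius"))
  p <- ggplot(df, aes(.data$x, .data$y))
  p <- if (attr(object, "semantics") == "node")
    p + geom_tile(aes(fill = .data$rvi_disp)) + scale_fill_viridis_c()
  else
    p + geom_point(aes(colour = .data$rvi_disp), size = 1.2) +
      scale_colour_viridis_c()
  p + coord_equal() +
    labs(title = ttl, x = "x (mm)", y = "y (mm)",
         fill = "RVI (ms)", colour = "RVI (ms)") +
    theme_minimal()
}

#' Plot a method-by-radius sweep
#'
#' Vulnerable-region size (or lowest RVI) as a function of the search radius,
#' one line per interpolation method.
#'
#' @param sweep An `rvi_sweep` tibble.
#' @param value Column to plot: `"size_mm2"`, `"lowest_rvi"` or `"n_below"`.
#' @return A ggplot.
#' @export
plot_sweep <- function(sweep, value = c("size_mm2", "lowest_rvi", "n_below")) {
  value <- match.arg(value)
  ggplot(sweep, aes(.data$radius, .data[[value]], colour = .data$method)) +
    geom_line() + geom_point() +
    labs(x = "search radius R (mm)", y = value, colour = NULL) +
    theme_minimal()
}
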
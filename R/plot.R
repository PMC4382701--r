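#' Tidy polygon table for plotting
#'
#' One row per cell-vertex, in drawing order, joined with the cell states —
#' ready for `ggplot2::geom_polygon(aes(x, y, group = cell))`.
#'
#' @param tissue a [leaf_tissue()].
#' @return A tibble with columns `cell`, `x`, `y`, `order` plus the state
#'   columns.
#' @export
tissue_polygons <- function(tissue) {
  tb <- tibble::tibble(
    cell = rep(tissue$states$cell, lengths(tissue$cells)),
    vertex = unlist(tissue$cells, use.names = FALSE),
    order = unlist(lapply(lengths(tissue$cells), seq_len), use.names = FALSE))
  tb$x <- tissue$vertices[tb$vertex, 1]
  tb$y <- tissue$vertices[tb$vertex, 2]
  dplyr::left_join(tb, tissue$states, by = "cell")
}

#' Plot a tissue
#'
#' Cell polygons filled by a state column.  The plot is drawn with the
#' adaxial side down (abaxial up), matching the internal coordinate
#' convention.
#'
#' @param object a [leaf_tissue()].
#' @param fill state column to map to fill (`"layer"`, `"identity"`, `"u"`,
#'   `"v"`, `"w"`, `"clock"`, ...).
#' @param ... ignored.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.leaf_tissue <- function(object, fill = "layer", ...) {
  df <- tissue_polygons(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$cell,
                                   fill = .data[[fill]])) +
    ggplot2::geom_polygon(colour = "grey20", linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = fill)
}

#' @rdname autoplot.leaf_tissue
#' @export
plot_tissue <- function(object, fill = "layer", ...) {
  autoplot.leaf_tissue(object, fill = fill, ...)
}

#' Plot a finished run
#'
#' Final tissue coloured by layer, with the recorded division lines drawn on
#' top.
#'
#' @param object a `leaf_run` from [run_simulation()].
#' @param fill state column for the cell fill.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.leaf_run <- function(object, fill = "layer", ...) {
  p <- autoplot.leaf_tissue(object$tissue, fill = fill)
  if (nrow(object$events)) {
    p <- p + ggplot2::geom_segment(
      data = object$events,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                   yend = .data$y2),
      inherit.aes = FALSE, colour = "white", linewidth = 0.3)
  }
  p
}

#' Write a vector rendering of a tissue
#'
#' Emits a standalone SVG with one polygon per cell, coloured by layer and
#' identity (adaxial L1 blue, abaxial L1 yellow, deeper layers in greys).
#'
#' @param tissue a [leaf_tissue()].
#' @param path output file path.
#' @param scale pixels per model unit.
#' @return The path, invisibly.
#' @export
write_svg_tissue <- function(tissue, path, scale = 20) {
  V <- tissue$vertices
  rng_x <- range(V[, 1]); rng_y <- range(V[, 2])
  pad <- 1
  wdt <- (diff(rng_x) + 2 * pad) * scale
  hgt <- (diff(rng_y) + 2 * pad) * scale
  px <- function(x) (x - rng_x[1] + pad) * scale
  py <- function(y) hgt - (y - rng_y[1] + pad) * scale  # svg y is down
  fill_of <- function(layer, identity) {
    if (!is.na(identity) && identity == "adaxial") return("#4472c4")
    if (!is.na(identity) && identity == "abaxial") return("#ffc000")
    switch(ifelse(is.na(layer), "inner", layer),
           L2 = "#c8d4c8", L3 = "#aebfae", "#dddddd")
  }
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f" viewBox="0 0 %.0f %.0f">',
    wdt, hgt, wdt, hgt))
  for (i in seq_along(tissue$cells)) {
    cyc <- tissue$cells[[i]]
    pts <- paste(sprintf("%.2f,%.2f", px(V[cyc, 1]), py(V[cyc, 2])),
                 collapse = " ")
    lines <- c(lines, sprintf(
      '<polygon points="%s" fill="%s" stroke="#333333" stroke-width="0.8"/>',
      pts, fill_of(tissue$states$layer[i], tissue$states$identity[i])))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}
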
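#' Render a heterogeneity map
#'
#' Draws a trait-combination matrix as a raster of one colour per
#' combination label, empty (`NA`) positions left blank, with grid lines
#' at the region boundaries.  A legend decodes the labels unless the
#' combination count exceeds `max_legend` (large trait sets can have
#' over a hundred combinations, at which point a legend is unreadable
#' and a region report is the better tool; a note is emitted instead).
#' 3D matrices are drawn as one panel per z-slice.
#'
#' @param m a [trait_matrix()].
#' @param region_size optional region extents for the grid overlay.
#' @param max_legend suppress the legend when `C` exceeds this (default
#'   20).
#' @param palette function mapping a count to colours (default
#'   [grDevices::hcl.colors()] on "Dark 3").
#' @param main plot title.
#' @return invisibly, the colour vector used per label.
#' @export
plot_heterogeneity_map <- function(m, region_size = NULL, max_legend = 20,
                                   palette = NULL, main = NULL) {
  assert_trait_matrix(m)
  d <- length(dim(m))
  C <- attr(m, "C")
  if (is.null(palette))
    palette <- function(n) grDevices::hcl.colors(n, "Dark 3")
  cols <- palette(C)
  if (d == 3L) {
    nz <- dim(m)[3L]
    op <- graphics::par(mfrow = c(1, nz))
    on.exit(graphics::par(op))
    for (k in seq_len(nz))
      plot_slice(label_array(m)[, , k], C, cols, region_size,
                 max_legend, attr(m, "decoding"),
                 main = paste0(if (is.null(main)) "z = " else
                   paste0(main, ", z = "), k))
    return(invisible(cols))
  }
  plot_slice(label_array(m), C, cols, region_size, max_legend,
             attr(m, "decoding"), main = main)
  invisible(cols)
}

plot_slice <- function(lab, C, cols, region_size, max_legend, decoding,
                       main = NULL) {
  nx <- nrow(lab); ny <- ncol(lab)
  graphics::image(x = seq_len(nx) - 0.5, y = seq_len(ny) - 0.5,
                  z = matrix(as.numeric(lab), nx, ny),
                  zlim = c(1, max(C, 2)), col = cols, useRaster = FALSE,
                  xlab = "x", ylab = "y", main = main, asp = 1)
  if (!is.null(region_size)) {
    rs <- rep_len(as.integer(region_size), 2L)
    graphics::abline(v = seq(0, nx, by = rs[1L]),
                     h = seq(0, ny, by = rs[2L]), col = "grey30")
  }
  if (C <= max_legend) {
    lbl <- vapply(decoding, paste, "", collapse = "+")
    graphics::legend("topright", legend = lbl, fill = cols, cex = 0.7,
                     bg = "white")
  } else {
    message("legend suppressed: ", C, " combinations (> ", max_legend,
            "); use region_report() to inspect compositions")
  }
}

#' @describeIn hta_test renders the fitted matrix with the fitted grid
#'   overlay and annotates HTA and the overall p-value.
#' @param x an `hta_test` object.
#' @param ... passed to [plot_heterogeneity_map()].
#' @export
plot.hta_test <- function(x, ...) {
  ttl <- sprintf("HTA = %.3f, overall P = %.3g", x$statistic$hta,
                 x$p$p_overall)
  plot_heterogeneity_map(x$matrix, region_size = x$region_size,
                         main = ttl, ...)
}
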
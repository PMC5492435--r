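#' Clinical map plots
#'
#' Color maps with the usual clinical presentations: sagittal curvature in
#' diopters over the analysis zone, pachymetry on a 300-900 um scale.
#' Requires ggplot2 (suggested).
#'
#' @param map a `curvature_map` or `pachymetry_map`.
#' @param limits color-scale limits; defaults to the clinical convention for
#'   the map type.
#' @return a ggplot object.
#' @export
plot_clinical_map <- function(map, limits = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_clinical_map requires the ggplot2 package")
  }
  if (inherits(map, "curvature_map")) {
    values <- map$values; lab <- "sagittal curvature (D)"
    if (is.null(limits)) limits <- c(40, 48)
  } else if (inherits(map, "pachymetry_map")) {
    values <- map$thickness_um; lab <- "pachymetry (µm)"
    if (is.null(limits)) limits <- c(300, 900)
  } else {
    stop("unsupported map type")
  }
  xy <- grid_xy(map$grid)
  df <- data.frame(x = as.vector(xy$x), y = as.vector(xy$y),
                   v = pmin(pmax(as.vector(values), limits[1]), limits[2]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$v)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_colour_gradientn(
      colours = c("#2c318f", "#00a4e0", "#5ab552", "#ffe14c", "#e8542c",
                  "#8f102c"),
      limits = limits, name = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
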
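#' Plot a raster layer
#'
#' Tile map of a [raster_layer()] in map coordinates, north up.
#'
#' @param object A [raster_layer()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.raster_layer <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85",
                                  name = object$semantics) +
    ggplot2::labs(x = "easting (m)", y = "northing (m)")
}

#' Plot per-class SCI frequency distributions
#'
#' Faceted histograms of SCI by forest-history class, the comparison that
#' shows plantation SCI concentrated low and primary-forest SCI high.
#'
#' @param object An `sci_distribution` tibble from
#'   [sci_distribution_by_class()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sci_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sci, y = .data$freq)) +
    ggplot2::geom_col(fill = "forestgreen") +
    ggplot2::facet_wrap(~forest_class) +
    ggplot2::labs(x = "SCI class", y = "relative frequency")
}

#' Plot validation samples
#'
#' FHD against SCI class for a sample table, with the per-class mean
#' overlaid — the qualitative check that structural condition tracks
#' foliage height diversity and where the relationship saturates.
#'
#' @param object A `validation_samples` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.validation_samples <- function(object, ...) {
  means <- summarize_fhd_by_sci(object)
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$sci),
                                       y = .data$fhd)) +
    ggplot2::geom_boxplot(outlier.size = 0.3, fill = "grey92") +
    ggplot2::geom_point(data = means,
                        ggplot2::aes(x = factor(.data$sci),
                                     y = .data$mean_fhd),
                        colour = "firebrick", size = 2) +
    ggplot2::labs(x = "SCI class", y = "FHD")
}

#' Plot a model comparison
#'
#' Dot plot of AIC by model, ascending.
#'
#' @param object A `model_comparison` tibble from [compare_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.model_comparison <- function(object, ...) {
  df <- dplyr::mutate(object,
                      name = factor(.data$name, rev(.data$name)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$aic, y = .data$name)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "AIC (maximum likelihood)", y = NULL)
}
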
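#' Plot raster layers, stacks and results with ggplot2
#'
#' `autoplot()` methods render the package's raster objects as
#' `geom_raster` maps in geographic coordinates: continuous layers
#' (suitability, consensus, uncertainty) with a viridis fill, binary ranges
#' as presence/absence, change maps with the conventional stable / lost /
#' gained palette, and stacks as one facet per variable. `autoplot()` on an
#' `enm_fit` shows each replicate's AUC against its TSS by algorithm, with
#' the default retention thresholds drawn in.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name rangecast-autoplot
NULL

raster_gg <- function(object) {
  df <- as_cell_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$longitude, .data$latitude)) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "Longitude", y = "Latitude")
}

#' @rdname rangecast-autoplot
#' @export
autoplot.env_layer <- function(object, ...) {
  raster_gg(object) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_viridis_c(name = object$name)
}

#' @rdname rangecast-autoplot
#' @export
autoplot.env_stack <- function(object, ...) {
  raster_gg(object) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::facet_wrap(~variable)
}

#' @rdname rangecast-autoplot
#' @export
autoplot.binary_layer <- function(object, ...) {
  df <- as_cell_tibble(object)
  df$value <- factor(df$value, c(0, 1), c("absence", "presence"))
  ggplot2::ggplot(df, ggplot2::aes(.data$longitude, .data$latitude)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_manual(values = c(absence = "grey85", presence = "forestgreen"),
                               name = NULL) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "Longitude", y = "Latitude")
}

#' @rdname rangecast-autoplot
#' @export
autoplot.change_layer <- function(object, ...) {
  df <- as_cell_tibble(object)
  df$value <- factor(df$value, 0:3, c("absent", "stable", "lost", "gained"))
  ggplot2::ggplot(df, ggplot2::aes(.data$longitude, .data$latitude)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_manual(
      values = c(absent = "grey90", stable = "forestgreen",
                 lost = "firebrick", gained = "steelblue"),
      name = "Range change"
    ) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "Longitude", y = "Latitude")
}

#' @rdname rangecast-autoplot
#' @param auc_min,tss_min Retention thresholds drawn as reference lines.
#' @export
autoplot.enm_fit <- function(object, auc_min = 0.75, tss_min = 0.7, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$auc, .data$tss,
                                             colour = .data$algorithm)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = auc_min, linetype = 2) +
    ggplot2::geom_hline(yintercept = tss_min, linetype = 2) +
    ggplot2::labs(x = "AUC (test)", y = "TSS (test)",
                  title = sprintf("%s: replicate performance", object$species))
}
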
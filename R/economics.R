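#' Timber value of a range area
#'
#' Converts suitable-habitat area to standing timber value under a static
#' price and a fixed merchantable volume per hectare:
#' `value = area_km2 * 100 (ha/km^2) * volume_density * price`. The default
#' volume density of 1.74 m^3/ha is an inventory estimate for large
#' (DBH >= 50 cm) *Dipteryx odorata* in Amazonian production forest; the
#' default price of 1000 USD/m^3 is an approximate cumaru export price.
#'
#' @param area_km2 Area in km^2 (>= 0; vectorized).
#' @param volume_density Merchantable volume in m^3 per hectare (> 0).
#' @param price Timber price in USD per m^3 (> 0).
#' @return Value in USD.
#' @export
#' @examples
#' timber_value_usd(1) # 174,000 USD per km^2 at the defaults
timber_value_usd <- function(area_km2, volume_density = 1.74, price = 1000) {
  if (any(area_km2 < 0)) abort("area must be >= 0")
  check_scalar(volume_density, "volume_density", 1e-12)
  check_scalar(price, "price", 1e-12)
  area_km2 * 100 * volume_density * price
}

#' Economic impact table from range-change summaries
#'
#' Per species, the net value at stake is
#' `timber_value_usd(lost) - timber_value_usd(gained)`: losses are positive
#' and range gains enter with a negative sign, so a species projected to
#' expand offsets the total. The gross loss (ignoring gains) is reported
#' alongside.
#'
#' @param summaries A tibble of change summaries (rows from
#'   [change_summary()]`$summary`, any number of species/periods).
#' @param volume_density,price See [timber_value_usd()].
#' @return A list with `by_species` (species, period_label, lost_km2,
#'   gained_km2, gross_loss_usd, net_usd) and `totals` (per period_label:
#'   total_net_usd, total_gross_loss_usd).
#' @export
economic_change_table <- function(summaries, volume_density = 1.74, price = 1000) {
  need <- c("species", "period_label", "lost_km2", "gained_km2")
  if (!all(need %in% names(summaries))) {
    abort(paste0("summaries must have columns: ", paste(need, collapse = ", ")))
  }
  by_species <- summaries |>
    dplyr::transmute(
      .data$species, .data$period_label, .data$lost_km2, .data$gained_km2,
      gross_loss_usd = timber_value_usd(.data$lost_km2, volume_density, price),
      net_usd = timber_value_usd(.data$lost_km2, volume_density, price) -
        timber_value_usd(.data$gained_km2, volume_density, price)
    )
  totals <- by_species |>
    dplyr::group_by(.data$period_label) |>
    dplyr::summarise(total_net_usd = sum(.data$net_usd),
                     total_gross_loss_usd = sum(.data$gross_loss_usd),
                     .groups = "drop")
  list(by_species = by_species, totals = totals)
}
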
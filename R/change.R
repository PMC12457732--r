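#' Lowest presence threshold (LPT)
#'
#' The minimum consensus suitability found at any known occurrence cell.
#' Binarizing at this value (inclusively) guarantees every occurrence cell
#' falls inside the predicted presence area.
#'
#' @param consensus A consensus (or any) [env_layer()].
#' @param presence_cells 0-based presence cell ids.
#' @return The LPT (numeric scalar). Errors, listing the offending cells,
#'   if any presence cell sits on nodata.
#' @export
lowest_presence_threshold <- function(consensus, presence_cells) {
  v <- as.vector(t(consensus$values))[presence_cells + 1]
  if (anyNA(v)) {
    abort(paste0("presence cell(s) on nodata: ",
                 paste(presence_cells[is.na(v)], collapse = ", ")))
  }
  min(v)
}

#' Binarize a suitability layer at a threshold
#'
#' @param layer An [env_layer()].
#' @param threshold Finite threshold; a cell is presence (1) iff its value
#'   is `>= threshold` (inclusive — required so that binarizing at the LPT
#'   covers every occurrence cell), else absence (0). Nodata is preserved.
#' @return A `binary_layer` ([env_layer()] subclass, values 0/1/NA) with
#'   attribute `threshold_used`.
#' @export
binarize <- function(layer, threshold) {
  check_scalar(threshold, "threshold")
  out <- env_layer(layer$grid, (layer$values >= threshold) * 1, name = "binary_range")
  structure(out, class = c("binary_layer", "env_layer"), threshold_used = threshold)
}

#' Categorical range-change map between two periods
#'
#' Cross-classifies two binary range rasters on a shared grid:
#' `stable` = presence in both, `lost` = present-only, `gained` =
#' scenario-only, `absent` = neither. Nodata in either input propagates.
#'
#' @param present,scenario `binary_layer`s on the same grid.
#' @return A `change_layer` ([env_layer()] subclass) with integer codes and
#'   a `codes` attribute `c(absent = 0, stable = 1, lost = 2, gained = 3)`.
#' @export
change_map <- function(present, scenario) {
  if (!grids_equal(present$grid, scenario$grid)) abort("grids differ")
  p <- present$values; s <- scenario$values
  v <- ifelse(p == 1 & s == 1, 1, ifelse(p == 1 & s == 0, 2, ifelse(p == 0 & s == 1, 3, 0)))
  out <- env_layer(present$grid, v, name = "range_change")
  structure(out, class = c("change_layer", "env_layer"),
            codes = c(absent = 0, stable = 1, lost = 2, gained = 3))
}

#' Total presence area of a binary range, in km^2
#'
#' Sums the curvature-corrected spherical area ([cell_area_km2()]) of every
#' presence cell.
#'
#' @param binary A `binary_layer`.
#' @return Area in km^2.
#' @export
total_area_km2 <- function(binary) {
  pres <- which(binary$values == 1, arr.ind = TRUE)
  if (nrow(pres) == 0) return(0)
  sum(cell_area_km2(binary$grid, pres[, "row"] - 1L))
}

#' Percent range change between two periods
#'
#' `(scenario_area - present_area) / present_area * 100`: positive values
#' are expansion, negative contraction, relative to the present-day range.
#'
#' @param present_area_km2,scenario_area_km2 Areas in km^2;
#'   `present_area_km2` must be > 0.
#' @return Percent change.
#' @export
percent_change <- function(present_area_km2, scenario_area_km2) {
  if (present_area_km2 <= 0) abort("percent change undefined for a zero present area")
  (scenario_area_km2 - present_area_km2) / present_area_km2 * 100
}

#' Range-change accounting for one species and scenario
#'
#' Builds the change map and the per-category curvature-corrected areas,
#' plus the two headline statistics: percent change of the total suitable
#' area and percent of the present area maintained (the stable share). By
#' construction `stable + lost = present area` and
#' `stable + gained = scenario area` exactly.
#'
#' @param present,scenario `binary_layer`s on a shared grid.
#' @param species,period_label Labels for the summary row.
#' @return A list with `map` (the `change_layer`) and `summary`, a one-row
#'   tibble: species, period_label, present_area_km2, scenario_area_km2,
#'   stable_km2, gained_km2, lost_km2, percent_change, percent_maintained.
#' @export
change_summary <- function(present, scenario, species = "species",
                           period_label = "scenario") {
  cm <- change_map(present, scenario)
  area_of <- function(code) {
    cells <- which(cm$values == code, arr.ind = TRUE)
    if (nrow(cells) == 0) 0 else sum(cell_area_km2(cm$grid, cells[, "row"] - 1L))
  }
  stable <- area_of(1); lost <- area_of(2); gained <- area_of(3)
  present_area <- stable + lost
  scenario_area <- stable + gained
  list(
    map = cm,
    summary = tibble(
      species = species, period_label = period_label,
      present_area_km2 = present_area, scenario_area_km2 = scenario_area,
      stable_km2 = stable, gained_km2 = gained, lost_km2 = lost,
      percent_change = percent_change(present_area, scenario_area),
      percent_maintained = 100 * stable / present_area
    )
  )
}
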
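#' Clean and standardize occurrence records
#'
#' Applies the standard herbarium-data hygiene steps: records with missing
#' coordinates or the exact (0, 0) point are dropped as missing; coordinates
#' outside \[-180, 180\] x \[-90, 90\] are dropped as invalid; exact
#' duplicates on (species, longitude, latitude) are collapsed to the first
#' record in input order. Cleaning is idempotent.
#'
#' @param records A data frame with columns `species`, `longitude`,
#'   `latitude` and optionally `source`.
#' @return A list with `occurrences` (the cleaned tibble, original column
#'   set preserved) and `report`, a one-row tibble with counts `n_input`,
#'   `n_missing`, `n_invalid_coords`, `n_duplicates`, `n_retained` that
#'   always reconcile: `n_input = n_retained + removals`.
#' @export
#' @examples
#' raw <- tibble::tibble(
#'   species = "sp", longitude = c(-60, -60, NA, 200), latitude = c(-3, -3, 4, 10)
#' )
#' clean_occurrences(raw)$report
clean_occurrences <- function(records) {
  records <- as_tibble(records)
  need <- c("species", "longitude", "latitude")
  if (!all(need %in% names(records))) {
    abort("records must have columns species, longitude, latitude")
  }
  if (!"source" %in% names(records)) records$source <- NA_character_
  n_input <- nrow(records)
  lon <- suppressWarnings(as.numeric(records$longitude))
  lat <- suppressWarnings(as.numeric(records$latitude))
  records$longitude <- lon
  records$latitude <- lat

  missing <- is.na(lon) | is.na(lat) | is.na(records$species) |
    (!is.na(lon) & !is.na(lat) & lon == 0 & lat == 0)
  invalid <- !missing & (abs(lon) > 180 | abs(lat) > 90)
  keep1 <- records[!(missing | invalid), , drop = FALSE]
  dup <- duplicated(keep1[, c("species", "longitude", "latitude")])
  cleaned <- keep1[!dup, , drop = FALSE]

  report <- tibble(
    n_input = n_input,
    n_missing = sum(missing),
    n_invalid_coords = sum(invalid),
    n_duplicates = sum(dup),
    n_retained = nrow(cleaned)
  )
  list(occurrences = cleaned, report = report)
}

#' Map occurrence records to presence cells
#'
#' The modeling unit is the presence cell: the set of grid cells containing
#' at least one occurrence record. Records sharing a cell collapse to one
#' presence cell; records outside the grid are counted and excluded.
#'
#' @param occurrences A cleaned occurrence tibble (`longitude`, `latitude`).
#' @param grid An [env_grid()].
#' @return Sorted integer vector of distinct 0-based cell ids, with
#'   attribute `n_outside` (records that fell off the grid). Errors if no
#'   record falls inside the grid.
#' @export
rasterize_presences <- function(occurrences, grid) {
  cells <- cell_from_lonlat(grid, occurrences$longitude, occurrences$latitude)
  n_outside <- sum(is.na(cells))
  cells <- sort(unique(cells[!is.na(cells)]))
  if (length(cells) == 0) abort("no occurrence record falls inside the grid")
  structure(cells, n_outside = n_outside)
}
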
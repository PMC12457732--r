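#' Per-cell standard-deviation (uncertainty) map
#'
#' Summarizes disagreement among member rasters — per-GCM consensus maps
#' (across-GCM uncertainty) or per-algorithm sub-ensembles (across-algorithm
#' uncertainty) — as the per-cell standard deviation of member values.
#' Sample SD (divisor n - 1) by default; a cell is nodata when fewer than
#' two members have data there.
#'
#' @param members A list of >= 2 [env_layer()]s on a shared grid, ideally
#'   named by member label.
#' @param sample_sd Use the n - 1 divisor (default TRUE); FALSE gives the
#'   population SD (divisor n).
#' @return An `uncertainty_layer` ([env_layer()] subclass) with attribute
#'   `member_labels`.
#' @export
#' @examples
#' g <- env_grid(2, 2, 0, 0, 1, 1)
#' sd_map(list(a = env_layer(g, matrix(0.2, 2, 2)),
#'             b = env_layer(g, matrix(0.4, 2, 2))))$values[1, 1]
sd_map <- function(members, sample_sd = TRUE) {
  if (length(members) < 2) abort("need at least 2 member rasters")
  grid <- members[[1]]$grid
  for (l in members) if (!grids_equal(grid, l$grid)) abort("members are on different grids")
  n <- matrix(0, grid$n_rows, grid$n_cols)
  s1 <- matrix(0, grid$n_rows, grid$n_cols)
  s2 <- matrix(0, grid$n_rows, grid$n_cols)
  for (l in members) {
    v <- l$values
    ok <- !is.na(v)
    v[!ok] <- 0
    n <- n + ok
    s1 <- s1 + v
    s2 <- s2 + v^2
  }
  mean_ <- s1 / n
  ss <- pmax(s2 - n * mean_^2, 0) # guards tiny negative fp residue
  out <- ss / (if (sample_sd) n - 1 else n)
  out[n < 2] <- NA
  out <- env_layer(grid, sqrt(out), name = "uncertainty_sd")
  structure(out, class = c("uncertainty_layer", "env_layer"),
            member_labels = names(members) %||% as.character(seq_along(members)))
}

#' Across-algorithm uncertainty from an `enm_fit`
#'
#' Builds one consensus per algorithm from its retained replicates, then
#' maps the per-cell SD across those per-algorithm ensembles.
#'
#' @param retained A retained replicate tibble (see [filter_replicates()]),
#'   with `algorithm`, `tss`, `prediction` columns.
#' @param species Label passed through to the member ensembles.
#' @return An `uncertainty_layer`; errors if fewer than two algorithms are
#'   represented.
#' @export
algorithm_uncertainty <- function(retained, species = "species") {
  algs <- unique(retained$algorithm)
  if (length(algs) < 2) abort("need retained replicates from >= 2 algorithms")
  members <- lapply(stats::setNames(algs, algs), function(a) {
    weighted_consensus(retained[retained$algorithm == a, , drop = FALSE],
                       species = species)
  })
  sd_map(members)
}
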
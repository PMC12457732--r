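#' Range-normalize a suitability layer
#'
#' Rescales a replicate's prediction to span exactly \[0, 1\] over its
#' non-nodata cells: `x' = (x - min) / (max - min)`. Every retained
#' replicate is standardized this way before entering the weighted
#' consensus, so algorithms with different native score scales are
#' commensurable.
#'
#' @param layer An [env_layer()].
#' @return The normalized [env_layer()]. A constant layer is an error: a
#'   constant prediction cannot pass the TSS filter, so reaching one here
#'   indicates a pipeline bug.
#' @export
range_normalize <- function(layer) {
  v <- layer$values
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(rng[1]) || diff(rng) == 0) {
    abort("cannot range-normalize a constant (or empty) layer")
  }
  env_layer(layer$grid, (v - rng[1]) / diff(rng), name = layer$name)
}

#' Squared-TSS weighted consensus of replicate predictions
#'
#' The ensemble rule: each member layer is range-normalized, then combined
#' per cell as \deqn{C = \sum_i w_i x_i / \sum_i w_i, \quad w_i = TSS_i^2,}
#' giving better-performing replicates more influence. A cell that is
#' nodata in any member is nodata in the consensus (mask intersection), so
#' no cell is silently averaged over fewer members;
#' `renormalize_nodata = TRUE` switches to per-cell reweighting over the
#' members that do have data.
#'
#' @param members A tibble (or data frame) with a `prediction` list-column
#'   of [env_layer()]s on a shared grid and a `tss` column, all TSS > 0 —
#'   typically the output of [filter_replicates()] / [project_enm()].
#' @param species,period_label,gcm_label Labels stamped on the result.
#' @param normalize Range-normalize members first (default TRUE).
#' @param renormalize_nodata Per-cell weight renormalization instead of
#'   mask intersection (default FALSE).
#' @return A `consensus_layer` (an [env_layer()] subclass) with attributes
#'   `member_count` and `weight_sum`.
#' @export
#' @examples
#' g <- env_grid(2, 2, 0, 0, 1, 1)
#' members <- tibble::tibble(
#'   prediction = list(env_layer(g, matrix(c(1, 0, 1, 0), 2)),
#'                     env_layer(g, matrix(c(0, 0, 1, 1), 2))),
#'   tss = c(0.8, 0.7)
#' )
#' weighted_consensus(members, normalize = FALSE)$values
weighted_consensus <- function(members, species = "species",
                               period_label = NULL, gcm_label = NULL,
                               normalize = TRUE, renormalize_nodata = FALSE) {
  if (nrow(members) < 1) abort("need at least one ensemble member")
  if (!all(c("prediction", "tss") %in% names(members))) {
    abort("members must have 'prediction' and 'tss' columns")
  }
  if (any(members$tss <= 0)) abort("all member TSS values must be > 0")
  layers <- members$prediction
  grid <- layers[[1]]$grid
  for (l in layers) if (!grids_equal(grid, l$grid)) abort("members are on different grids")
  if (normalize) layers <- lapply(layers, range_normalize)
  w <- members$tss^2
  num <- matrix(0, grid$n_rows, grid$n_cols)
  den <- matrix(0, grid$n_rows, grid$n_cols)
  any_na <- matrix(FALSE, grid$n_rows, grid$n_cols)
  for (i in seq_along(layers)) {
    v <- layers[[i]]$values
    na <- is.na(v)
    any_na <- any_na | na
    v[na] <- 0
    num <- num + w[i] * v
    den <- den + w[i] * !na
  }
  c_vals <- num / den
  if (!renormalize_nodata) c_vals[any_na] <- NA else c_vals[den == 0] <- NA
  out <- env_layer(grid, c_vals, name = "consensus")
  structure(
    c(out, list(species = species,
                period_label = period_label %||% attr(members, "period_label"),
                gcm_label = gcm_label)),
    class = c("consensus_layer", "env_layer"),
    member_count = nrow(members), weight_sum = sum(w)
  )
}

#' Per-GCM consensus ensembles
#'
#' Groups projected members by their source climate model label and applies
#' [weighted_consensus()] within each group — the basis of the across-GCM
#' uncertainty maps. Groups that end up empty are omitted with a warning.
#'
#' @param members As in [weighted_consensus()], with a `gcm_label` column.
#' @inheritParams weighted_consensus
#' @return A named list of `consensus_layer`s, keyed by GCM label.
#' @export
per_gcm_consensus <- function(members, species = "species", period_label = NULL) {
  if (!"gcm_label" %in% names(members)) abort("members must carry a gcm_label column")
  labels <- unique(members$gcm_label)
  out <- list()
  for (g in labels) {
    grp <- members[members$gcm_label == g, , drop = FALSE]
    if (nrow(grp) == 0) { warn(sprintf("no members for GCM '%s'", g)); next }
    out[[g]] <- weighted_consensus(grp, species = species,
                                   period_label = period_label, gcm_label = g)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
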
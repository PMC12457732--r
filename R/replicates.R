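#' Build replicated calibration/test datasets
#'
#' Implements the replication protocol: per repetition, a 70/30 split of the
#' presence cells (uniform, without replacement; the calibration share is
#' `round(train_frac * n)`, half-up) and pseudoabsence cells drawn uniformly
#' without replacement from cells where no record of the species was found —
#' in a 1:1 ratio with the presences of each partition, train and test
#' background disjoint. One partition is drawn per repetition and shared by
#' all algorithms, giving `length(algorithms) * n_reps` replicate
#' specifications.
#'
#' @param presence_cells Integer vector of 0-based presence cell ids
#'   (>= 5 cells).
#' @param background_pool Integer vector of candidate pseudoabsence cell
#'   ids: non-nodata cells with no presence record.
#' @param n_reps Repetitions per algorithm (default 100).
#' @param train_frac Calibration fraction of presence cells (default 0.7).
#' @param algorithms Algorithm names (default all five).
#' @param seed Integer master seed; per-repetition seeds are derived.
#' @return A tibble with one row per algorithm x repetition: `algorithm`,
#'   `rep`, `seed`, and list-columns `train_presence`, `test_presence`,
#'   `train_background`, `test_background`.
#' @export
make_replicates <- function(presence_cells, background_pool, n_reps = 100,
                            train_frac = 0.7, algorithms = ENM_ALGORITHMS,
                            seed = 1) {
  presence_cells <- as.integer(presence_cells)
  n <- length(presence_cells)
  if (n < 5) abort("need at least 5 presence cells")
  if (any(background_pool %in% presence_cells)) {
    abort("background_pool must exclude all presence cells")
  }
  check_scalar(train_frac, "train_frac", 0, 1)
  n_train <- floor(train_frac * n + 0.5)
  if (n_train < 1 || n_train >= n) abort("train_frac leaves an empty partition")
  if (length(background_pool) < n) {
    abort(sprintf("background pool (%d cells) smaller than the presence count (%d)",
                  length(background_pool), n))
  }
  parts <- lapply(seq_len(n_reps), function(r) {
    set.seed(derive_seed(seed, "replicate", r))
    tr <- sample(presence_cells, n_train)
    te <- setdiff(presence_cells, tr)
    bg <- sample(background_pool, n)
    list(train_presence = sort(tr), test_presence = sort(te),
         train_background = sort(bg[seq_len(n_train)]),
         test_background = sort(bg[(n_train + 1):n]))
  })
  tidyr::expand_grid(algorithm = algorithms, rep = seq_len(n_reps)) |>
    dplyr::mutate(
      seed = purrr::map_int(.data$rep, ~ derive_seed(seed, "fit", .x)),
      train_presence = purrr::map(.data$rep, ~ parts[[.x]]$train_presence),
      test_presence = purrr::map(.data$rep, ~ parts[[.x]]$test_presence),
      train_background = purrr::map(.data$rep, ~ parts[[.x]]$train_background),
      test_background = purrr::map(.data$rep, ~ parts[[.x]]$test_background)
    )
}

#' Fit the replicated multi-algorithm ensemble for one species
#'
#' For each replicate: fits the algorithm on the calibration partition,
#' projects it over the full stack, and evaluates rank AUC and the TSS
#' (with its sensitivity-specificity threshold) on the held-out 30% test
#' partition only, reading test scores off the prediction raster.
#'
#' @param stack The present-period [env_stack()] (fitting stack).
#' @param presence_cells 0-based presence cell ids (from
#'   [rasterize_presences()]).
#' @param variables Variables to use (default: all layers of `stack` —
#'   normally the output of [spearman_select()]).
#' @inheritParams make_replicates
#' @param species Species label carried through to results.
#' @return An `enm_fit` object: list with `$replicates` (tibble: algorithm,
#'   rep, seed, auc, tss, threshold, sensitivity, specificity, flagged,
#'   and list-columns `model`, `prediction`), plus the grid, presence
#'   cells, variables and labels. `tidy()` extracts the metrics table;
#'   `glance()` one summary row.
#' @export
fit_enm <- function(stack, presence_cells, variables = names(stack$layers),
                    n_reps = 100, train_frac = 0.7,
                    algorithms = ENM_ALGORITHMS, seed = 1,
                    species = "species") {
  missing <- setdiff(variables, names(stack$layers))
  if (length(missing)) abort(paste0("stack lacks variable(s): ", paste(missing, collapse = ", ")))
  sub <- env_stack(stack$grid, stack$layers[variables],
                   period_label = stack$period_label, gcm_label = stack$gcm_label)
  ok <- valid_cells(sub)
  on_nodata <- setdiff(presence_cells, ok)
  if (length(on_nodata)) {
    warn(sprintf("dropping %d presence cell(s) on nodata", length(on_nodata)))
    presence_cells <- setdiff(presence_cells, on_nodata)
  }
  pool <- setdiff(ok, presence_cells)
  specs <- make_replicates(presence_cells, pool, n_reps = n_reps,
                           train_frac = train_frac, algorithms = algorithms,
                           seed = seed)
  cellmat <- stack_values(sub)
  rows <- purrr::pmap(specs, function(algorithm, rep, seed,
                                      train_presence, test_presence,
                                      train_background, test_background) {
    model <- fit_algorithm(algorithm,
                           cellmat[train_presence + 1, , drop = FALSE],
                           cellmat[train_background + 1, , drop = FALSE],
                           seed = seed)
    pred <- predict_raster(model, sub)
    score_at <- function(cells) as.vector(t(pred$values))[cells + 1]
    sp <- score_at(test_presence); sb <- score_at(test_background)
    th <- select_threshold_tss(sp, sb)
    tibble(auc = auc_score(sp, sb), tss = th$tss, threshold = th$threshold,
           sensitivity = th$sensitivity, specificity = th$specificity,
           flagged = model$flagged,
           model = list(model), prediction = list(pred))
  })
  replicates <- dplyr::bind_cols(specs[, c("algorithm", "rep", "seed")],
                                 dplyr::bind_rows(rows))
  structure(
    list(species = species, replicates = replicates,
         grid = sub$grid, variables = variables,
         presence_cells = as.integer(presence_cells),
         period_label = sub$period_label, gcm_label = sub$gcm_label,
         n_reps = n_reps, train_frac = train_frac, seed = seed),
    class = "enm_fit"
  )
}

#' @export
print.enm_fit <- function(x, ...) {
  cat(sprintf("<enm_fit> '%s': %d replicates (%s), %d presence cells, period '%s'\n",
              x$species, nrow(x$replicates),
              paste(unique(x$replicates$algorithm), collapse = ", "),
              length(x$presence_cells), x$period_label))
  invisible(x)
}

#' Project fitted replicates onto another period/scenario stack
#'
#' Re-applies each (already evaluated) replicate model to a past or future
#' environmental stack; evaluation metrics are those earned on the present
#' test partition and are carried along unchanged.
#'
#' @param fit An `enm_fit`.
#' @param stack The target [env_stack()] (e.g. LGM or an SSP scenario from
#'   one GCM).
#' @param replicates Optionally a filtered subset of `fit$replicates`
#'   (e.g. from [filter_replicates()]); defaults to all.
#' @return A tibble like `fit$replicates` with `prediction` replaced by
#'   layers on the target stack, plus `period_label` and `gcm_label`
#'   columns taken from the stack.
#' @export
project_enm <- function(fit, stack, replicates = fit$replicates) {
  if (!grids_equal(fit$grid, stack$grid)) abort("target stack grid differs from the fitted grid")
  replicates |>
    dplyr::mutate(
      prediction = purrr::map(.data$model, predict_raster, stack = stack),
      period_label = stack$period_label,
      gcm_label = stack$gcm_label
    )
}
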
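#' Run the full ensemble niche-modeling workflow
#'
#' Orchestrates, per species: occurrence cleaning and rasterization to
#' presence cells on the present grid; Spearman pruning of the predictors;
#' replicated fitting of the five algorithms with 1:1 pseudoabsences and
#' 70/30 splits; AUC/TSS evaluation and filtering; squared-TSS weighted
#' consensus for the present and (by projecting the retained models) for
#' each scenario period — pooled across GCMs by default and per GCM;
#' LPT binarization; gain/loss/stable change maps with curvature-corrected
#' areas and percent-change statistics; across-GCM and across-algorithm
#' uncertainty maps; and the timber-value impact table.
#'
#' A fatal error in one species aborts that species with a logged reason
#' and the run continues with the others. Results are bit-reproducible
#' given the inputs and `seed`: per-species, per-stage child seeds are
#' derived with [derive_seed()], so adding a species never perturbs
#' another's draws.
#'
#' @param occurrences Raw occurrence tibble (`species`, `longitude`,
#'   `latitude`, optional `source`) covering any number of species.
#' @param present_stack The present-period [env_stack()].
#' @param scenario_stacks List of [env_stack()]s for past/future periods;
#'   each carries its `period_label` and `gcm_label` (several stacks may
#'   share a period label, one per GCM).
#' @param spearman_threshold Collinearity ceiling for [spearman_select()]
#'   (default 0.6).
#' @param n_reps,train_frac,algorithms,auc_min,tss_min Modeling and
#'   filtering parameters (defaults 100, 0.7, all five algorithms, 0.75,
#'   0.7).
#' @param volume_density,price Timber parameters for
#'   [economic_change_table()].
#' @param seed Master seed.
#' @param keep_models Keep fitted model objects in the result (default
#'   FALSE to bound memory).
#' @return An `enm_run` list: `manifest` (per-species counts, seeds,
#'   selected variables, LPT), `species` (per-species list with the fit
#'   metrics, consensus/binary/change/uncertainty layers), `summaries`
#'   (all change-summary rows), `economics`, and `errors` (named reasons
#'   for any aborted species).
#' @export
run_enm_pipeline <- function(occurrences, present_stack, scenario_stacks = list(),
                             spearman_threshold = 0.6,
                             n_reps = 100, train_frac = 0.7,
                             algorithms = ENM_ALGORITHMS,
                             auc_min = 0.75, tss_min = 0.7,
                             volume_density = 1.74, price = 1000,
                             seed = 1, keep_models = FALSE) {
  cleaned <- clean_occurrences(occurrences)
  variables <- spearman_select(present_stack, threshold = spearman_threshold)
  species_list <- unique(cleaned$occurrences$species)
  periods <- unique(vapply(scenario_stacks, `[[`, "", "period_label"))

  results <- list(); manifest <- list(); summaries <- list(); errors <- list()
  for (sp in species_list) {
    res <- tryCatch(
      run_one_species(sp, cleaned$occurrences, present_stack, scenario_stacks,
                      variables, n_reps, train_frac, algorithms,
                      auc_min, tss_min, derive_seed(seed, "species", sp),
                      keep_models),
      error = function(e) structure(conditionMessage(e), class = "species_error")
    )
    if (inherits(res, "species_error")) {
      errors[[sp]] <- as.character(res)
      message(sprintf("species '%s' aborted: %s", sp, res))
      next
    }
    results[[sp]] <- res
    manifest[[sp]] <- res$manifest
    summaries[[sp]] <- res$summaries
  }
  summaries <- dplyr::bind_rows(summaries)
  economics <- if (nrow(summaries) > 0) {
    economic_change_table(summaries, volume_density, price)
  }
  structure(
    list(manifest = dplyr::bind_rows(manifest),
         clean_report = cleaned$report,
         variables = as.character(variables),
         species = results, summaries = summaries,
         economics = economics, errors = errors,
         periods = periods, seed = seed,
         version = as.character(utils::packageVersion("rangecast"))),
    class = "enm_run"
  )
}

run_one_species <- function(sp, occ, present_stack, scenario_stacks, variables,
                            n_reps, train_frac, algorithms, auc_min, tss_min,
                            seed, keep_models) {
  occ_sp <- occ[occ$species == sp, , drop = FALSE]
  presence <- rasterize_presences(occ_sp, present_stack$grid)
  fit <- fit_enm(present_stack, presence, variables = variables,
                 n_reps = n_reps, train_frac = train_frac,
                 algorithms = algorithms, seed = seed, species = sp)
  retained <- filter_replicates(fit$replicates, auc_min = auc_min, tss_min = tss_min)
  consensus_present <- weighted_consensus(retained, species = sp,
                                          period_label = present_stack$period_label)
  lpt <- lowest_presence_threshold(consensus_present, presence)
  binary_present <- binarize(consensus_present, lpt)
  alg_uncertainty <- tryCatch(algorithm_uncertainty(retained, species = sp),
                              error = function(e) NULL)

  period_labels <- unique(vapply(scenario_stacks, `[[`, "", "period_label"))
  scenarios <- list(); summaries <- list()
  for (pl in period_labels) {
    stacks_p <- scenario_stacks[vapply(scenario_stacks, `[[`, "", "period_label") == pl]
    projected <- dplyr::bind_rows(lapply(stacks_p, function(st) project_enm(fit, st, retained)))
    consensus <- weighted_consensus(projected, species = sp, period_label = pl)
    by_gcm <- per_gcm_consensus(projected, species = sp, period_label = pl)
    gcm_sd <- if (length(by_gcm) >= 2) sd_map(by_gcm)
    binary <- binarize(consensus, lpt)
    chg <- change_summary(binary_present, binary, species = sp, period_label = pl)
    scenarios[[pl]] <- list(consensus = consensus, per_gcm = by_gcm,
                            gcm_uncertainty = gcm_sd, binary = binary,
                            change = chg$map)
    summaries[[pl]] <- chg$summary
  }
  metrics <- tidy_replicates(fit$replicates)
  if (!keep_models) fit$replicates <- metrics
  list(
    fit = fit, metrics = metrics,
    retained_metrics = tidy_replicates(retained),
    retention = attr(retained, "retention"),
    consensus_present = consensus_present,
    binary_present = binary_present,
    algorithm_uncertainty = alg_uncertainty,
    lpt = lpt, scenarios = scenarios,
    summaries = dplyr::bind_rows(summaries),
    manifest = tibble(
      species = sp, seed = seed,
      n_records = nrow(occ_sp), n_presence_cells = length(presence),
      n_variables = length(variables),
      n_candidate_replicates = nrow(metrics),
      n_retained_replicates = nrow(tidy_replicates(retained)),
      lpt = lpt
    )
  )
}

tidy_replicates <- function(replicates) {
  replicates[, intersect(c("algorithm", "rep", "seed", "auc", "tss", "threshold",
                           "sensitivity", "specificity", "flagged"),
                         names(replicates)), drop = FALSE]
}

#' @export
print.enm_run <- function(x, ...) {
  cat(sprintf("<enm_run> %d species, %d scenario period(s), seed %d (rangecast %s)\n",
              length(x$species), length(x$periods), x$seed, x$version))
  if (length(x$errors)) {
    cat("aborted species:", paste(names(x$errors), collapse = ", "), "\n")
  }
  print(x$manifest)
  invisible(x)
}
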
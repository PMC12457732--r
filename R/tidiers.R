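#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` on an `enm_fit` returns the one-row-per-
#' replicate metrics table (algorithm, rep, seed, auc, tss, threshold,
#' sensitivity, specificity, flagged); `glance()` a one-row summary with
#' mean metrics and the retention rate at the default AUC/TSS filter.
#' On an `enm_run`, `tidy()` returns all change-summary rows and `glance()`
#' one row per species from the manifest.
#'
#' @param x An `enm_fit` or `enm_run`.
#' @param auc_min,tss_min Filter thresholds used for the retention-rate
#'   column of `glance.enm_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.enm_fit <- function(x, ...) {
  as_tibble(tidy_replicates(x$replicates))
}

#' @rdname tidiers
#' @export
glance.enm_fit <- function(x, auc_min = 0.75, tss_min = 0.7, ...) {
  m <- x$replicates
  tibble(
    species = x$species, period_label = x$period_label,
    n_replicates = nrow(m),
    n_algorithms = length(unique(m$algorithm)),
    mean_auc = mean(m$auc), mean_tss = mean(m$tss),
    retention_rate = mean(m$auc >= auc_min & m$tss >= tss_min),
    n_presence_cells = length(x$presence_cells)
  )
}

#' @rdname tidiers
#' @export
tidy.enm_run <- function(x, ...) as_tibble(x$summaries)

#' @rdname tidiers
#' @export
glance.enm_run <- function(x, ...) as_tibble(x$manifest)
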
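#' Rank-based AUC (Mann-Whitney)
#'
#' The probability that a randomly drawn presence score exceeds a randomly
#' drawn background score, ties counted 1/2 — computed exactly from mid-ranks
#' rather than by trapezoid integration of an ROC curve.
#'
#' @param scores_presence,scores_background Non-empty numeric score vectors
#'   at test presence / background cells.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc_score(c(0.8, 0.4), c(0.6, 0.2)) # 3 of 4 pairs correctly ordered
auc_score <- function(scores_presence, scores_background) {
  n1 <- length(scores_presence); n0 <- length(scores_background)
  if (n1 == 0 || n0 == 0) abort("both score vectors must be non-empty")
  r <- rank(c(scores_presence, scores_background), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity-specificity threshold selection and TSS
#'
#' Scans every unique observed score as a candidate threshold (a cell is
#' predicted present iff its score is >= the threshold) and returns the
#' threshold maximizing sensitivity + specificity, i.e. maximizing the true
#' skill statistic TSS = sensitivity + specificity - 1. Ties are broken by
#' the smallest such threshold, which favours sensitivity. The alternative
#' reading of the sensitivity-specificity rule — the threshold where
#' sensitivity and specificity cross — is available as `method = "equal"`.
#'
#' @inheritParams auc_score
#' @param method `"max"` (maximize sens + spec; default) or `"equal"`
#'   (minimize |sens - spec|, ties by larger TSS then smaller threshold).
#' @return A one-row tibble: `threshold`, `tss`, `sensitivity`,
#'   `specificity`.
#' @export
select_threshold_tss <- function(scores_presence, scores_background,
                                 method = c("max", "equal")) {
  method <- match.arg(method)
  if (length(scores_presence) == 0 || length(scores_background) == 0) {
    abort("both score vectors must be non-empty")
  }
  cand <- sort(unique(c(scores_presence, scores_background)))
  sens <- vapply(cand, function(t) mean(scores_presence >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(scores_background < t), numeric(1))
  # ties among maxima go to the smallest threshold; the 1e-12 guard keeps
  # floating-point noise in the sens/spec sums from deciding a tie
  s <- sens + spec
  i <- switch(method,
    max = which(s >= max(s) - 1e-12)[1],
    equal = order(abs(sens - spec), -s, cand)[1]
  )
  tibble(threshold = cand[i], tss = sens[i] + spec[i] - 1,
         sensitivity = sens[i], specificity = spec[i])
}

#' Filter fitted replicates on AUC and TSS
#'
#' Only replicates with `auc >= auc_min` AND `tss >= tss_min` (both
#' inclusive) enter the ensemble; row order is preserved. Flagged
#' replicates (non-convergent or degenerate fits) are dropped first.
#'
#' @param replicates A tibble with at least `algorithm`, `auc`, `tss`
#'   columns (as produced by [fit_enm()]'s `$replicates`).
#' @param auc_min,tss_min Inclusive retention thresholds
#'   (defaults 0.75 and 0.7).
#' @return The retained sub-tibble, with per-algorithm retention counts in
#'   attribute `retention`. Errors if nothing is retained (no ensemble is
#'   possible).
#' @export
filter_replicates <- function(replicates, auc_min = 0.75, tss_min = 0.7) {
  check_scalar(auc_min, "auc_min", 0, 1); check_scalar(tss_min, "tss_min", -1, 1)
  if (!all(c("algorithm", "auc", "tss") %in% names(replicates))) {
    abort("replicates must have columns algorithm, auc, tss")
  }
  ok <- replicates$auc >= auc_min & replicates$tss >= tss_min
  if ("flagged" %in% names(replicates)) ok <- ok & !replicates$flagged
  retained <- replicates[ok, , drop = FALSE]
  if (nrow(retained) == 0) {
    abort(sprintf("no replicate passed AUC >= %g and TSS >= %g: no ensemble possible",
                  auc_min, tss_min))
  }
  retention <- dplyr::count(
    dplyr::mutate(replicates, retained = ok),
    .data$algorithm, .data$retained, name = "n"
  )
  structure(retained, retention = retention)
}
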
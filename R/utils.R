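#' Derive a reproducible child seed from a master seed and labels
#'
#' Child seeds keep independent pipeline stages (and independent species)
#' decoupled: adding a species or a stage never perturbs the random draws of
#' another. The derivation is a plain polynomial string hash folded into the
#' master seed, reduced modulo a Mersenne prime so the result is always a
#' valid positive 32-bit integer seed.
#'
#' @param seed Master integer seed.
#' @param ... Labels (character or integer scalars) identifying the stage,
#'   e.g. `derive_seed(1, "fit", "species_a", 12)`.
#' @return A positive integer seed, deterministic in its inputs.
#' @export
#' @examples
#' derive_seed(1, "fit", "virtual_species", 3)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  m <- 2147483647 # 2^31 - 1
  h <- as.double(seed) %% m
  for (tok in list(...)) {
    for (code in utf8ToInt(paste0("|", as.character(tok)))) {
      h <- (h * 31 + code) %% m
    }
  }
  as.integer(h %% (m - 1L) + 1)
}

# shared input check: a numeric scalar in a closed range
check_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a finite numeric scalar in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}
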
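# Virtual-species simulator: synthetic environments with controllable
# spatial structure and rank correlation, a known Gaussian-product niche
# truth surface, and occurrence sampling from it. Everything downstream of
# data download can be exercised against a known answer.

# smooth standard-normal-ish field: coarse white noise bilinearly
# upsampled; `smoothness` is the coarse-cell width in fine cells
smooth_noise_field <- function(n_rows, n_cols, smoothness) {
  if (smoothness <= 1) {
    return(matrix(rnorm(n_rows * n_cols), n_rows, n_cols))
  }
  cr <- max(2, ceiling(n_rows / smoothness) + 1)
  cc <- max(2, ceiling(n_cols / smoothness) + 1)
  coarse <- matrix(rnorm(cr * cc), cr, cc)
  # bilinear interpolation of the coarse lattice onto the fine grid
  ri <- seq(1, cr, length.out = n_rows)
  ci <- seq(1, cc, length.out = n_cols)
  r0 <- pmin(floor(ri), cr - 1); rf <- ri - r0
  c0 <- pmin(floor(ci), cc - 1); cf <- ci - c0
  out <- matrix(0, n_rows, n_cols)
  for (j in seq_len(n_cols)) {
    a <- coarse[cbind(r0, c0[j])] * (1 - rf) + coarse[cbind(r0 + 1, c0[j])] * rf
    b <- coarse[cbind(r0, c0[j] + 1)] * (1 - rf) + coarse[cbind(r0 + 1, c0[j] + 1)] * rf
    out[, j] <- a * (1 - cf[j]) + b * cf[j]
  }
  out
}

# exact standard-normal scores of a field's ranks (ties mid-ranked);
# used so that rank-correlation targets can be set through the Gaussian
# copula relation rho_pearson = 2 sin(pi * rho_spearman / 6)
normal_scores <- function(m) {
  r <- rank(as.vector(m), ties.method = "average")
  matrix(qnorm(r / (length(r) + 1)), nrow(m), ncol(m))
}

#' Simulate a synthetic environmental stack
#'
#' Generates `n_vars` environmental variables on a WGS 84 grid, each a
#' deterministic function of the seed: a random linear latitude/longitude
#' gradient plus spatially smoothed Gaussian noise, rescaled to a
#' variable-specific unit range. Designated pairs of variables are made
#' rank-correlated by Gaussian-copula mixing of their normal scores, with a
#' realized Spearman rho within about +/-0.1 of the target, so that
#' collinearity pruning can be exercised; all other pairs use independent
#' noise.
#'
#' @param n_rows,n_cols Grid dimensions (>= 2 each).
#' @param n_vars Number of variables (default 4), named `var1..varN`.
#' @param extent Numeric `c(west, south, east, north)` in degrees; cells
#'   must come out square in degrees.
#' @param smoothness Spatial correlation length of the noise component, in
#'   cells (0 = white noise).
#' @param gradient_weight,noise_weight Relative weight of the deterministic
#'   gradient vs the smoothed noise.
#' @param correlated_pairs List of `list(var_i, var_j, rho)` triples with
#'   `rho` in \[-1, 1\]; `var_j` is rebuilt as a copula mixture of `var_i`
#'   and its own smooth noise.
#' @param seed Integer seed; same spec + seed gives bit-identical stacks.
#' @param period_label,gcm_label Labels stamped on the stack.
#' @return An [env_stack()] with no nodata cells.
#' @export
#' @examples
#' st <- simulate_environment(30, 30, n_vars = 3, seed = 7,
#'   correlated_pairs = list(list("var1", "var3", 0.9)))
#' cor(as.vector(st$layers$var1), as.vector(st$layers$var3), method = "spearman")
simulate_environment <- function(n_rows, n_cols, n_vars = 4,
                                 extent = c(-75, -15, -45, 15),
                                 smoothness = 5,
                                 gradient_weight = 1, noise_weight = 1,
                                 correlated_pairs = list(),
                                 seed = 1,
                                 period_label = "present",
                                 gcm_label = "observed") {
  grid <- env_grid(n_rows, n_cols, extent[1], extent[2], extent[3], extent[4])
  for (p in correlated_pairs) {
    if (length(p) != 3 || abs(as.numeric(p[[3]])) > 1) {
      abort("each correlated pair must be list(var_i, var_j, rho) with rho in [-1, 1]")
    }
  }
  set.seed(derive_seed(seed, "simulate_environment"))
  lat <- matrix(rep(seq(1, 0, length.out = n_rows), n_cols), n_rows, n_cols)
  lon <- matrix(rep(seq(0, 1, length.out = n_cols), each = n_rows), n_rows, n_cols)
  raw <- vector("list", n_vars)
  names(raw) <- paste0("var", seq_len(n_vars))
  for (k in seq_len(n_vars)) {
    a <- runif(1, -1, 1); b <- runif(1, -1, 1)
    f <- gradient_weight * (a * lat + b * lon) +
      noise_weight * smooth_noise_field(n_rows, n_cols, smoothness)
    raw[[k]] <- (f - mean(f)) / sd(f)
  }
  for (p in correlated_pairs) {
    vi <- as.character(p[[1]]); vj <- as.character(p[[2]])
    if (!vi %in% names(raw) || !vj %in% names(raw)) abort("correlated pair names unknown")
    rho_p <- 2 * sin(pi * as.numeric(p[[3]]) / 6)
    zi <- normal_scores(raw[[vi]])
    zj <- normal_scores(raw[[vj]])
    raw[[vj]] <- rho_p * zi + sqrt(1 - rho_p^2) * zj
  }
  # distinct, plausible unit scales per variable (temperature-like, mm-like ...)
  layers <- lapply(seq_len(n_vars), function(k) 20 + 4 * k + (2 + k) * raw[[k]])
  names(layers) <- names(raw)
  env_stack(grid, layers, period_label = period_label, gcm_label = gcm_label)
}

#' True suitability of a virtual species (Gaussian-product niche)
#'
#' The truth model against which recovered consensus maps are judged: per
#' cell, \deqn{S = \prod_v \exp\{-(e_v - \mu_v)^2 / (2\sigma_v^2)\}} over
#' the variables named in `optima`, i.e. independent Gaussian response
#' curves multiplied together. `S` is in (0, 1\] and equals 1 exactly when
#' every variable sits at its optimum.
#'
#' @param stack An [env_stack()] containing every variable in `optima`.
#' @param optima Named numeric vector of niche optima (variable units).
#' @param breadths Named numeric vector of niche breadths (> 0), same names
#'   as `optima`.
#' @return An [env_layer()] of true suitability.
#' @export
true_suitability <- function(stack, optima, breadths) {
  if (!setequal(names(optima), names(breadths)) || is.null(names(optima))) {
    abort("optima and breadths must be named identically")
  }
  if (any(breadths <= 0)) abort("all niche breadths must be > 0")
  missing <- setdiff(names(optima), names(stack$layers))
  if (length(missing)) {
    abort(paste0("stack is missing variable(s): ", paste(missing, collapse = ", ")))
  }
  s <- matrix(1, stack$grid$n_rows, stack$grid$n_cols)
  for (v in names(optima)) {
    s <- s * exp(-(stack$layers[[v]] - optima[[v]])^2 / (2 * breadths[[v]]^2))
  }
  env_layer(stack$grid, s, name = "true_suitability")
}

#' Sample virtual occurrence records from a suitability surface
#'
#' Draws `n_presences` distinct cells either with inclusion probability
#' proportional to suitability (`"probabilistic"`) or as the top-suitability
#' cells with ties broken by row-major cell order (`"top_cells"`), and
#' returns cell-center coordinates as an occurrence table.
#'
#' @param suitability An [env_layer()] with values in \[0, 1\].
#' @param n_presences Number of occurrence records (>= 1).
#' @param mode `"probabilistic"` or `"top_cells"`.
#' @param species Species label for the table.
#' @param seed Integer seed (probabilistic mode).
#' @return A tibble with columns `species`, `longitude`, `latitude`,
#'   `source`.
#' @export
sample_occurrences <- function(suitability, n_presences,
                               mode = c("probabilistic", "top_cells"),
                               species = "virtual_species", seed = 1) {
  mode <- match.arg(mode)
  check_scalar(n_presences, "n_presences", 1)
  s <- as.vector(t(suitability$values)) # 0-based id order
  ok <- which(!is.na(s) & s > 0)
  if (length(ok) < n_presences) {
    abort(sprintf("cannot draw %d presences from %d cells with positive suitability",
                  n_presences, length(ok)))
  }
  if (mode == "top_cells") {
    cells <- ok[order(-s[ok], ok)][seq_len(n_presences)] - 1L
  } else {
    set.seed(derive_seed(seed, "sample_occurrences", species))
    cells <- sample(ok, n_presences, prob = s[ok]) - 1L
  }
  ctr <- cell_center(suitability$grid, sort(cells))
  tibble(species = species, longitude = ctr$longitude,
         latitude = ctr$latitude, source = "simulated")
}

#' Emulate a climate-scenario stack by perturbing a present-day stack
#'
#' Stands in for past/future climate layers: each variable is shifted by a
#' constant multiple of its standard deviation plus smooth spatially
#' structured noise, on the same grid. Different `seed`/`shift_sd` choices
#' emulate different GCMs and emission scenarios.
#'
#' @param stack The present-day [env_stack()].
#' @param shift_sd Systematic shift, in per-variable standard deviations
#'   (sign = direction of change).
#' @param noise_sd Smooth noise amplitude, in per-variable SDs.
#' @param smoothness Correlation length of the perturbation noise, cells.
#' @param seed Integer seed.
#' @param period_label,gcm_label Labels for the new stack.
#' @return A perturbed [env_stack()] on the same grid.
#' @export
perturb_stack <- function(stack, shift_sd = 0.5, noise_sd = 0.25, smoothness = 5,
                          seed = 1, period_label = "scenario", gcm_label = "GCM-1") {
  set.seed(derive_seed(seed, "perturb_stack", period_label, gcm_label))
  layers <- lapply(stack$layers, function(v) {
    s <- sd(v, na.rm = TRUE)
    v + shift_sd * s +
      noise_sd * s * smooth_noise_field(nrow(v), ncol(v), smoothness)
  })
  env_stack(stack$grid, layers, period_label = period_label, gcm_label = gcm_label)
}
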
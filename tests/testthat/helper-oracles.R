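# Independent brute-force oracles, kept deliberately naive so they stay
# independent of the implementation paths they check.

# AUC by explicit pair counting
oracle_auc <- function(pres, bg) {
  wins <- 0
  for (p in pres) for (b in bg) {
    wins <- wins + if (p > b) 1 else if (p == b) 0.5 else 0
  }
  wins / (length(pres) * length(bg))
}

# exhaustive threshold scan maximizing sens + spec, smallest threshold wins
oracle_threshold_tss <- function(pres, bg) {
  best <- NULL
  for (t in sort(unique(c(pres, bg)))) {
    sens <- sum(pres >= t) / length(pres)
    spec <- sum(bg < t) / length(bg)
    if (is.null(best) || sens + spec > best$sum + 1e-12) {
      best <- list(threshold = t, sum = sens + spec,
                   tss = sens + spec - 1, sensitivity = sens, specificity = spec)
    }
  }
  best
}

# Spearman rho = Pearson correlation of mid-ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# spherical cell area by numerical integration of the surface element
# A = R^2 * dlambda * int_phi_s^phi_n cos(phi) dphi
oracle_cell_area <- function(lat_s, lat_n, dlon_deg, R = 6371.0072) {
  f <- stats::integrate(function(phi) cos(phi), lat_s * pi / 180, lat_n * pi / 180,
                        rel.tol = 1e-12)
  R^2 * (dlon_deg * pi / 180) * f$value
}
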
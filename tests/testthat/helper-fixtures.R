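# Shared fixtures, built in code at test time.

# small unit grid: 4 x 4 cells of 0.5 degree over [0, 2] x [0, 2]
unit_grid <- function() env_grid(4, 4, west = 0, south = 0, east = 2, north = 2)

# tiny two-variable stack with a known nodata hole
tiny_stack <- function(nodata_cells = integer(0)) {
  g <- unit_grid()
  v1 <- matrix(seq_len(16), 4, 4, byrow = TRUE)
  v2 <- matrix(seq(0, 30, length.out = 16), 4, 4, byrow = TRUE)
  if (length(nodata_cells)) {
    for (id in nodata_cells) {
      v1[id %/% 4 + 1, id %% 4 + 1] <- NA
      v2[id %/% 4 + 1, id %% 4 + 1] <- NA
    }
  }
  env_stack(g, list(a = v1, b = v2))
}

# the well-sampled virtual species used for niche-recovery checks:
# 60 x 60 grid, two informative variables plus a correlated nuisance
# variable, narrow Gaussian niche ~1 SD off-center, 120 presences
vs_case <- function(seed) {
  stack <- simulate_environment(60, 60, n_vars = 3, seed = seed,
                                correlated_pairs = list(list("var1", "var3", 0.9)))
  optima <- c(var1 = 27, var2 = 32)
  breadths <- c(var1 = 1.5, var2 = 2.0)
  suit <- true_suitability(stack, optima, breadths)
  occ <- sample_occurrences(suit, 120, seed = seed, species = "vs")
  list(stack = stack, suit = suit, occ = occ,
       presence = rasterize_presences(occ, stack$grid))
}

layer_vec <- function(layer) as.vector(t(layer$values))
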
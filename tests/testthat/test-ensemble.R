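consensus_members <- function(values_list, tss, g = unit_grid()) {
  tibble::tibble(
    prediction = lapply(values_list, function(v) env_layer(g, v)),
    tss = tss
  )
}

test_that("range normalization rescales to exactly [0, 1]", {
  g <- env_grid(3, 1, 0, 0, 1, 3)
  l <- env_layer(g, matrix(c(0.2, 0.45, 0.7), 3, 1))
  out <- range_normalize(l)
  expect_equal(as.vector(out$values), c(0, 0.5, 1))
  already <- env_layer(g, matrix(c(0, 0.5, 1), 3, 1))
  expect_equal(range_normalize(already)$values, already$values)
  expect_error(range_normalize(env_layer(g, matrix(0.3, 3, 1))), "constant")
})

test_that("squared-TSS weighting reproduces the hand-checked cell value", {
  g <- unit_grid()
  m <- consensus_members(list(matrix(1, 4, 4), matrix(0, 4, 4)), c(0.8, 0.7))
  cons <- weighted_consensus(m, normalize = FALSE)
  expect_equal(cons$values[1, 1], (0.64 * 1 + 0.49 * 0) / 1.13)
  expect_equal(cons$values[1, 1], 0.56637, tolerance = 1e-5)
  expect_equal(attr(cons, "member_count"), 2)
  expect_equal(attr(cons, "weight_sum"), 0.64 + 0.49)
})

test_that("a single member or identical members pass through unchanged", {
  set.seed(5)
  v <- matrix(runif(16), 4, 4)
  one <- weighted_consensus(consensus_members(list(v), 0.9), normalize = FALSE)
  expect_equal(one$values, v)
  same <- weighted_consensus(consensus_members(list(v, v, v), c(0.9, 0.8, 0.71)),
                             normalize = FALSE)
  expect_equal(same$values, v)
})

test_that("consensus is a convex, permutation- and scale-invariant combination", {
  set.seed(6)
  vals <- lapply(1:4, function(i) matrix(runif(16), 4, 4))
  tss <- c(0.9, 0.85, 0.8, 0.75)
  cons <- weighted_consensus(consensus_members(vals, tss), normalize = FALSE)
  lo <- Reduce(pmin, vals); hi <- Reduce(pmax, vals)
  expect_true(all(cons$values >= lo - 1e-12 & cons$values <= hi + 1e-12))
  perm <- c(3, 1, 4, 2)
  cons_p <- weighted_consensus(consensus_members(vals[perm], tss[perm]),
                               normalize = FALSE)
  expect_equal(cons_p$values, cons$values, tolerance = 1e-12)
  # scaling every TSS by a constant scales every weight by its square
  # and leaves the weighted mean unchanged
  cons_s <- weighted_consensus(consensus_members(vals, tss / 2), normalize = FALSE)
  expect_equal(cons_s$values, cons$values, tolerance = 1e-12)
})

test_that("nodata defaults to mask intersection with per-cell reweighting opt-in", {
  g <- unit_grid()
  v1 <- matrix(0.4, 4, 4); v1[1, 1] <- NA
  v2 <- matrix(0.8, 4, 4)
  m <- consensus_members(list(v1, v2), c(0.8, 0.8))
  strict <- weighted_consensus(m, normalize = FALSE)
  expect_true(is.na(strict$values[1, 1]))
  expect_equal(strict$values[2, 2], 0.6)
  renorm <- weighted_consensus(m, normalize = FALSE, renormalize_nodata = TRUE)
  expect_equal(renorm$values[1, 1], 0.8) # only the member with data
})

test_that("invalid member sets are rejected", {
  g2 <- env_grid(2, 2, 0, 0, 1, 1)
  bad <- tibble::tibble(prediction = list(env_layer(unit_grid(), matrix(1, 4, 4)),
                                          env_layer(g2, matrix(1, 2, 2))),
                        tss = c(0.8, 0.8))
  expect_error(weighted_consensus(bad, normalize = FALSE), "different grids")
  zero <- consensus_members(list(matrix(1, 4, 4)), 0)
  expect_error(weighted_consensus(zero), "> 0")
})

test_that("per-GCM grouping partitions the consensus", {
  set.seed(8)
  vals <- lapply(1:4, function(i) matrix(runif(16), 4, 4))
  m <- consensus_members(vals, c(0.9, 0.8, 0.85, 0.75))
  m$gcm_label <- c("G1", "G1", "G2", "G2")
  by_gcm <- per_gcm_consensus(m, species = "sp")
  expect_setequal(names(by_gcm), c("G1", "G2"))
  # one GCM only: equals the plain consensus of all members
  m1 <- m; m1$gcm_label <- "G1"
  expect_equal(per_gcm_consensus(m1)$G1$values,
               weighted_consensus(m)$values, tolerance = 1e-12)
  # each group's consensus stays inside its own members' envelope per cell
  for (g in c("G1", "G2")) {
    idx <- which(m$gcm_label == g)
    nl <- lapply(vals[idx], function(v) range_normalize(env_layer(unit_grid(), v))$values)
    lo <- Reduce(pmin, nl); hi <- Reduce(pmax, nl)
    expect_true(all(by_gcm[[g]]$values >= lo - 1e-12 &
                      by_gcm[[g]]$values <= hi + 1e-12))
  }
})
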
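bin_layer <- function(v, g = unit_grid(), threshold = 0.5) {
  binarize(env_layer(g, v), threshold)
}

test_that("LPT is the minimum consensus value over occupied cells", {
  g <- unit_grid()
  v <- matrix(0, 4, 4)
  v[1, 1] <- 0.55; v[2, 3] <- 0.31; v[4, 4] <- 0.72
  cons <- env_layer(g, v)
  cells <- c(0L, 6L, 15L) # row-major ids of the three cells above
  expect_equal(lowest_presence_threshold(cons, cells), 0.31)
  expect_equal(lowest_presence_threshold(cons, 15L), 0.72)
  v[2, 3] <- NA
  expect_error(lowest_presence_threshold(env_layer(g, v), cells), "nodata")
})

test_that("binarization is inclusive and preserves nodata", {
  g <- unit_grid()
  v <- matrix(seq(0.1, 1.6, 0.1), 4, 4, byrow = TRUE)
  v[3, 3] <- NA
  b <- binarize(env_layer(g, v), 0.5)
  expect_equal(b$values[1, 4], 0) # 0.4 < 0.5
  expect_equal(b$values[2, 1], 1) # exactly at the threshold -> presence
  expect_true(is.na(b$values[3, 3]))
  expect_true(all(binarize(env_layer(g, abs(v) + 1), 0)$values == 1, na.rm = TRUE))
  expect_true(all(binarize(env_layer(g, v), 99)$values == 0, na.rm = TRUE))
})

test_that("binarizing a consensus at its LPT covers every occurrence cell", {
  case <- vs_case(31)
  s <- case$suit
  b <- binarize(s, lowest_presence_threshold(s, case$presence))
  expect_true(all(layer_vec(b)[case$presence + 1] == 1))
})

test_that("change maps cross-classify the two binary rasters", {
  p <- bin_layer(matrix(c(rep(1, 8), rep(0, 8)), 4, 4, byrow = TRUE))
  s <- bin_layer(matrix(c(rep(1, 4), rep(0, 8), rep(1, 4)), 4, 4, byrow = TRUE))
  cm <- change_map(p, s)
  expect_equal(sum(cm$values == 1), 4)  # stable
  expect_equal(sum(cm$values == 2), 4)  # lost
  expect_equal(sum(cm$values == 3), 4)  # gained
  expect_equal(sum(cm$values == 0), 4)  # absent
  # identity comparison: only stable and absent remain
  cm_id <- change_map(p, p)
  expect_setequal(unique(as.vector(cm_id$values)), c(0, 1))
  # scenario collapse: losses equal the present footprint
  gone <- bin_layer(matrix(0, 4, 4))
  expect_equal(sum(change_map(p, gone)$values == 2), sum(p$values == 1))
  expect_error(change_map(p, bin_layer(matrix(1, 2, 2), env_grid(2, 2, 0, 0, 1, 1))),
               "grids differ")
})

test_that("areas are curvature-corrected sums over presence cells", {
  empty <- bin_layer(matrix(0, 4, 4))
  expect_equal(total_area_km2(empty), 0)
  # one 0.5 degree cell touching the equator
  g <- env_grid(4, 4, 0, -1, 2, 1)
  one <- matrix(0, 4, 4); one[2, 1] <- 1 # row covering 0..0.5 degrees
  expect_equal(total_area_km2(bin_layer(one, g)), oracle_cell_area(0, 0.5, 0.5),
               tolerance = 1e-9)
  expect_equal(total_area_km2(bin_layer(one, g)), 3091.0, tolerance = 1e-3)
  # additivity over disjoint presence sets
  two <- matrix(0, 4, 4); two[3, 2] <- 1
  both <- one + two
  expect_equal(total_area_km2(bin_layer(both, g)),
               total_area_km2(bin_layer(one, g)) + total_area_km2(bin_layer(two, g)))
})

test_that("percent change follows the (scenario - present)/present rule", {
  expect_equal(percent_change(100, 110), 10)
  expect_equal(percent_change(150, 150), 0)
  expect_equal(percent_change(200, 150), -25)
  expect_error(percent_change(0, 10), "zero present")
})

test_that("change summaries reconcile areas and percentages exactly", {
  set.seed(12)
  g <- env_grid(6, 6, -3, -3, 3, 3)
  p <- binarize(env_layer(g, matrix(runif(36), 6, 6)), 0.4)
  s <- binarize(env_layer(g, matrix(runif(36), 6, 6)), 0.5)
  out <- change_summary(p, s, species = "sp", period_label = "future")$summary
  expect_equal(out$stable_km2 + out$lost_km2, out$present_area_km2)
  expect_equal(out$stable_km2 + out$gained_km2, out$scenario_area_km2)
  expect_equal(out$present_area_km2, total_area_km2(p), tolerance = 1e-12)
  expect_equal(out$scenario_area_km2, total_area_km2(s), tolerance = 1e-12)
  expect_gte(out$percent_maintained, 0); expect_lte(out$percent_maintained, 100)
  # identity scenario: exact zeros / hundred
  idt <- change_summary(p, p)$summary
  expect_identical(idt$percent_change, 0)
  expect_identical(idt$percent_maintained, 100)
})

test_that("percent maintained is 100 iff the present footprint is kept", {
  g <- unit_grid()
  p <- bin_layer(matrix(c(rep(1, 4), rep(0, 12)), 4, 4, byrow = TRUE))
  s_all <- bin_layer(matrix(1, 4, 4))
  expect_equal(change_summary(p, s_all)$summary$percent_maintained, 100)
  s_part <- bin_layer(matrix(c(1, 1, 0, 0, rep(0, 12)), 4, 4, byrow = TRUE))
  expect_lt(change_summary(p, s_part)$summary$percent_maintained, 100)
})
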
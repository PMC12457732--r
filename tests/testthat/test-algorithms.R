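mat2 <- function(a, b) matrix(c(a, b), ncol = 2, dimnames = list(NULL, c("x", "y")))

test_that("bioclim envelope score follows the mid-rank percentile rule", {
  train <- mat2(1:10, seq(2, 20, 2))
  m <- fit_algorithm("bioclim", train)
  # per-variable medians (even n: mid-rank percentile is exactly 0.5
  # anywhere between the two central values)
  expect_equal(predict_cells(m, mat2(5.5, 11)), 1)
  # query below/above any training range -> 0
  expect_equal(predict_cells(m, mat2(0, 11)), 0)
  expect_equal(predict_cells(m, mat2(5.5, 21)), 0)
  # worked percentile: value 3 in 1..10 -> p = (2 + 0.5)/10, score 0.5
  m1 <- fit_algorithm("bioclim", matrix(1:10, ncol = 1, dimnames = list(NULL, "x")))
  expect_equal(predict_cells(m1, matrix(3, dimnames = list(NULL, "x"))), 0.5)
  # odd n: the exact median scores 1
  modd <- fit_algorithm("bioclim", matrix(1:9, ncol = 1, dimnames = list(NULL, "x")))
  expect_equal(predict_cells(modd, matrix(5, dimnames = list(NULL, "x"))), 1)
})

test_that("bioclim is invariant to variable order and monotone transforms", {
  set.seed(1)
  train <- mat2(rnorm(15), runif(15))
  q <- mat2(rnorm(6), runif(6))
  m <- fit_algorithm("bioclim", train)
  swapped <- train[, c("y", "x")]
  m2 <- fit_algorithm("bioclim", swapped)
  expect_equal(predict_cells(m, q), predict_cells(m2, q[, c("y", "x")]))
  # strictly monotone transform applied jointly to training and query
  tr3 <- train; tr3[, "x"] <- exp(tr3[, "x"])
  q3 <- q; q3[, "x"] <- exp(q3[, "x"])
  expect_equal(predict_cells(fit_algorithm("bioclim", tr3), q3),
               predict_cells(m, q), tolerance = 1e-12)
})

test_that("domain Gower similarity matches hand computations", {
  train <- mat2(c(0, 1), c(0, 1))
  m <- fit_algorithm("domain", train)
  expect_equal(predict_cells(m, mat2(0, 0)), 1) # a training point
  expect_equal(predict_cells(m, mat2(0.5, 0.5)), 0.5) # d = 0.5 to each
  expect_equal(predict_cells(m, mat2(2, 2)), 0) # d_min = 1, clamped
  # variable reordering leaves scores unchanged
  m2 <- fit_algorithm("domain", train[, c("y", "x")])
  q <- mat2(c(0.2, 0.9), c(0.4, 0.1))
  expect_equal(predict_cells(m, q), predict_cells(m2, q[, c("y", "x")]))
})

test_that("zero-range variables contribute 0 when equal, 1 otherwise", {
  train <- matrix(c(5, 5, 0, 1), ncol = 2, dimnames = list(NULL, c("x", "y")))
  m <- fit_algorithm("domain", train)
  expect_equal(predict_cells(m, mat2(5, 0)), 1)
  # x differs from the constant training value: that term is 1
  expect_equal(predict_cells(m, mat2(6, 0)), 0.5)
})

test_that("glm behaves like a logistic regression should", {
  set.seed(2)
  x <- mat2(rnorm(40), rnorm(40))
  m <- fit_algorithm("glm", x[1:20, ], x[21:40, ])
  expect_equal(mean(predict_cells(m, x)), 0.5, tolerance = 0.15)
  # single informative covariate: predictions monotone in it
  pres <- mat2(rnorm(30, 1), rnorm(30))
  bg <- mat2(rnorm(30, -1), rnorm(30))
  m2 <- fit_algorithm("glm", pres, bg)
  q <- mat2(seq(-3, 3, length.out = 20), rep(0, 20))
  expect_true(all(diff(predict_cells(m2, q)) > 0))
})

test_that("svm and rf scores are deterministic and separate separable classes", {
  set.seed(3)
  pres <- mat2(rnorm(50, 4), rnorm(50, 4))
  bg <- mat2(rnorm(50, 0), rnorm(50, 0))
  q <- rbind(pres[1:20, ], bg[1:20, ])
  for (alg in c("svm", "rf")) {
    m <- fit_algorithm(alg, pres, bg, seed = 7)
    m2 <- fit_algorithm(alg, pres, bg, seed = 7)
    expect_identical(predict_cells(m, q), predict_cells(m2, q))
    expect_gt(auc_score(predict_cells(m, pres[21:50, , drop = FALSE]),
                        predict_cells(m, bg[21:50, , drop = FALSE])), 0.95)
  }
})

test_that("a point duplicated in both classes is maximally ambiguous", {
  amb <- mat2(rep(1, 20), rep(2, 20))
  set.seed(4)
  pres <- rbind(amb, mat2(rnorm(20, 3), rnorm(20, 5)))
  bg <- rbind(amb, mat2(rnorm(20, -3), rnorm(20, -1)))
  m <- fit_algorithm("rf", pres, bg, seed = 5)
  expect_equal(predict_cells(m, mat2(1, 2)), 0.5, tolerance = 0.15)
})

test_that("raster prediction propagates nodata and keeps locality", {
  st <- tiny_stack(nodata_cells = 6L)
  cells <- rasterize_presences(
    tibble::tibble(species = "s", longitude = c(0.2, 1.2, 1.7, 0.7, 0.2),
                   latitude = c(0.2, 0.7, 0.2, 1.7, 1.2)), st$grid)
  vals <- sapply(st$layers, function(v) as.vector(t(v)))
  colnames(vals) <- names(st$layers)
  m <- fit_algorithm("domain", vals[cells + 1, , drop = FALSE])
  pred <- predict_raster(m, st)
  expect_true(is.na(pred$values[2, 3])) # the nodata hole
  expect_false(anyNA(pred$values[-2, ]))
  # domain scores 1 at its own training presence cells
  expect_equal(layer_vec(pred)[cells + 1], rep(1, length(cells)))
  expect_error(predict_raster(m, env_stack(st$grid, list(a = st$layers$a))), "missing")
})
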
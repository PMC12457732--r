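test_that("replicate construction follows the 70/30, 1:1 protocol", {
  presence <- 0:9
  pool <- 20:80
  specs <- make_replicates(presence, pool, n_reps = 4, seed = 3)
  expect_equal(nrow(specs), 5 * 4) # algorithms x repetitions
  for (i in seq_len(nrow(specs))) {
    tr <- specs$train_presence[[i]]; te <- specs$test_presence[[i]]
    expect_length(tr, 7); expect_length(te, 3)
    expect_length(intersect(tr, te), 0)
    expect_setequal(c(tr, te), presence)
    # 1:1 pseudoabsence within each partition, all from the pool,
    # train and test background disjoint
    expect_length(specs$train_background[[i]], 7)
    expect_length(specs$test_background[[i]], 3)
    expect_true(all(c(specs$train_background[[i]], specs$test_background[[i]]) %in% pool))
    expect_length(intersect(specs$train_background[[i]], specs$test_background[[i]]), 0)
  }
  # the same repetition shares its partition across algorithms
  expect_identical(specs$train_presence[[1]], specs$train_presence[[5]])
})

test_that("replicate construction is seeded and validates inputs", {
  a <- make_replicates(0:9, 20:60, n_reps = 3, seed = 5)
  b <- make_replicates(0:9, 20:60, n_reps = 3, seed = 5)
  expect_identical(a, b)
  c <- make_replicates(0:9, 20:60, n_reps = 3, seed = 6)
  expect_false(identical(a$train_presence, c$train_presence))
  expect_error(make_replicates(0:3, 20:60), "at least 5")
  expect_error(make_replicates(0:9, 5:40), "exclude")
  expect_error(make_replicates(0:9, 20:25), "pool")
})

test_that("fitting evaluates on the held-out partition and is reproducible", {
  case <- vs_case(19)
  fit1 <- fit_enm(case$stack, case$presence, variables = c("var1", "var2"),
                  n_reps = 2, seed = 4, species = "vs")
  fit2 <- fit_enm(case$stack, case$presence, variables = c("var1", "var2"),
                  n_reps = 2, seed = 4, species = "vs")
  expect_equal(tidy(fit1), tidy(fit2))
  expect_equal(nrow(fit1$replicates), 10)
  expect_true(all(fit1$replicates$auc >= 0 & fit1$replicates$auc <= 1))
  expect_true(all(fit1$replicates$tss >= -1 & fit1$replicates$tss <= 1))
  # every prediction lies in [0, 1] on data cells
  for (p in fit1$replicates$prediction) {
    v <- p$values[!is.na(p$values)]
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("projection keeps metrics and re-scores the new stack", {
  case <- vs_case(23)
  fit <- fit_enm(case$stack, case$presence, variables = c("var1", "var2"),
                 n_reps = 2, algorithms = c("bioclim", "glm"), seed = 9)
  same <- project_enm(fit, case$stack)
  for (i in seq_len(nrow(same))) {
    expect_equal(same$prediction[[i]]$values, fit$replicates$prediction[[i]]$values,
                 tolerance = 1e-12)
  }
  shifted <- perturb_stack(case$stack, shift_sd = 1, seed = 2,
                           period_label = "future", gcm_label = "G9")
  proj <- project_enm(fit, shifted)
  expect_identical(unique(proj$period_label), "future")
  expect_identical(unique(proj$gcm_label), "G9")
  expect_identical(proj$auc, fit$replicates$auc) # metrics carried, not re-earned
  expect_false(identical(proj$prediction[[1]]$values, fit$replicates$prediction[[1]]$values))
  g2 <- env_grid(5, 5, 0, 0, 5, 5)
  expect_error(project_enm(fit, simulate_environment(5, 5, n_vars = 2, extent = c(0, 0, 5, 5))),
               "grid")
})

test_that("all five algorithms recover a sharply separable niche", {
  st <- simulate_environment(40, 40, n_vars = 2, seed = 7)
  suit <- true_suitability(st, c(var1 = 30, var2 = 36), c(var1 = 1.5, var2 = 2.0))
  occ <- sample_occurrences(suit, 60, mode = "top_cells", species = "vs")
  pres <- rasterize_presences(occ, st$grid)
  fit <- fit_enm(st, pres, n_reps = 10, seed = 21, species = "vs")
  by_alg <- dplyr::summarise(dplyr::group_by(tidy(fit), algorithm),
                             mean_auc = mean(auc))
  expect_equal(nrow(by_alg), 5)
  expect_true(all(by_alg$mean_auc >= 0.9))
})
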
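test_that("boundary assignment follows the signed-side convention", {
  ds <- simulate_lv_replicates(list(c(4, 8), c(10, 8), c(15, 8)),
                               sigma = 0, n_steps = 20, seed = 1)
  # vertical line prey = 10: below or on the line -> group 1
  g <- assign_groups(ds, list(normal = c(1, 0), offset = 10))
  expect_equal(g$group, c(1L, 1L, 2L))
  expect_equal(g$replicate_id, c("lv1", "lv2", "lv3"))

  expect_warning(one <- assign_groups(ds, list(normal = c(1, 0),
                                               offset = 100)),
                 "one side")
  expect_true(all(one$group == 1L))
  expect_error(assign_groups(ds, list(normal = c(0, 0), offset = 1)),
               "degenerate")
  expect_error(assign_groups(ds, list(normal = 1, offset = 1)),
               "one entry per species")
})

test_that("two-regime synthetic data is grouped to its generative labels", {
  ds <- two_regime_dataset(seed = 42)
  g <- assign_groups(ds, list(normal = c(1, 0), offset = 10))
  lk <- setNames(g$group, g$replicate_id)
  expect_true(all(lk[startsWith(names(lk), "lv")] == 1L))
  expect_true(all(lk[startsWith(names(lk), "mv")] == 2L))
})

block_fits_for <- function(ds, target, theta = 0.5) {
  fits <- lapply(ds$replicates, function(r) {
    blk <- embed_series(r, embedding_spec(2, 1, 1, "block", target))
    smap_forecast(blk, theta = theta)
  })
  names(fits) <- names(ds$replicates)
  fits
}

test_that("identical replicates give zero-SE mean interaction trajectories", {
  ds <- simulate_lv_replicates(list(c(5, 10), c(5, 10), c(5, 10)),
                               sigma = 0, n_steps = 30, seed = 2)
  fits <- block_fits_for(ds, "prey")
  g <- data.frame(replicate_id = names(fits), group = 1L)
  tr <- mean_interaction_trajectories(fits, g, effect_of = "predator")
  expect_true(all(abs(tr$se) < 1e-10))
  expect_equal(unique(tr$n), 3)
})

test_that("the predation coefficient has the sign of the true interaction", {
  # Lotka-Volterra prey equation: dprey/dt = prey (a - b predator), so the
  # effect of predators on prey along the cycle is negative
  ds <- simulate_lv_replicates(list(c(5, 8), c(6, 9), c(7, 10)),
                               sigma = 0.02, n_steps = 50, seed = 8)
  fits <- block_fits_for(ds, "prey", theta = 2)
  g <- data.frame(replicate_id = names(fits), group = 1L)
  tr <- mean_interaction_trajectories(fits, g, effect_of = "predator")
  expect_lt(mean(tr$mean), 0)
})

test_that("the two coupling directions have opposite signs and groups differ", {
  ds <- two_regime_dataset(seed = 9, sigma = 0.02)
  g <- assign_groups(ds, list(normal = c(1, 0), offset = 10))
  # predators harm prey (negative coupling), prey feed predators (positive):
  # the two interaction directions trace opposite-sign mean trajectories
  fits_prey <- block_fits_for(ds, "prey", theta = 1)
  fits_pred <- block_fits_for(ds, "predator", theta = 1)
  tr_down <- mean_interaction_trajectories(fits_prey, g,
                                           effect_of = "predator")
  tr_up <- mean_interaction_trajectories(fits_pred, g, effect_of = "prey")
  for (gr in 1:2) {
    expect_lt(mean(tr_down$mean[tr_down$group == gr]), 0)
    expect_gt(mean(tr_up$mean[tr_up$group == gr]), 0)
  }
  # the regimes differ in predation strength, and the extracted
  # predator-on-prey effect separates the groups accordingly
  m1 <- mean(tr_down$mean[tr_down$group == 1])
  m2 <- mean(tr_down$mean[tr_down$group == 2])
  expect_gt(abs(m1 - m2), 0.05)
  expect_warning(
    mean_interaction_trajectories(fits_prey[1], g, effect_of = "predator"),
    "fewer than 2")
})

test_that("within/between MAE summary counts and degenerate cases", {
  ds <- simulate_lv_replicates(list(c(5, 8), c(6, 9), c(14, 8), c(15, 9)),
                               sigma = 0.02, n_steps = 30, seed = 4)
  recs <- pairwise_table(ds, theta = 0.5, horizons = 1:2)
  g <- assign_groups(ds, list(normal = c(1, 0), offset = 10))
  s <- within_between_mae(recs, g)
  expect_equal(s$n_pairs[s$category == "within_1"], 2L)
  expect_equal(s$n_pairs[s$category == "within_2"], 2L)
  expect_equal(s$n_pairs[s$category == "between"], 8L)

  # identical replicates: within and between errors coincide
  di <- simulate_lv_replicates(list(c(5, 8), c(5, 8), c(5, 8), c(5, 8)),
                               sigma = 0, n_steps = 30, seed = 4)
  recs_i <- pairwise_table(di, theta = 0.5, horizons = 1:2)
  gi <- data.frame(replicate_id = names(di$replicates),
                   group = c(1L, 1L, 2L, 2L))
  si <- within_between_mae(recs_i, gi)
  expect_equal(si$mean_mae[si$category == "between"],
               si$mean_mae[si$category == "within_1"], tolerance = 1e-10)

  g_empty <- data.frame(replicate_id = names(di$replicates),
                        group = c(1L, 1L, 1L, 1L))
  w <- testthat::capture_warnings(se <- within_between_mae(recs_i, g_empty))
  expect_match(w, "within_2|between", all = TRUE)
  expect_equal(se$n_pairs[se$category == "within_2"], 0L)
  expect_equal(se$n_pairs[se$category == "between"], 0L)
})

test_that("two-regime data cross-predicts worse between groups than within", {
  ds <- two_regime_dataset(seed = 13, sigma = 0.02, n_steps = 40,
                           n_per_group = 2)
  recs <- pairwise_table(ds, theta = 1, horizons = 1:3)
  g <- assign_groups(ds, list(normal = c(1, 0), offset = 10))
  s <- within_between_mae(recs, g)
  expect_gt(s$mean_mae[s$category == "between"],
            max(s$mean_mae[s$category != "between"]))
})
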
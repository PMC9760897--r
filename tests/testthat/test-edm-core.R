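test_that("embedding has the expected row count and lag structure", {
  rs <- replicate_series("a", 0:9, matrix(1:10, ncol = 1,
                                          dimnames = list(NULL, "x")))
  b <- embed_series(rs, embedding_spec(E = 2, tau = 1, tp = 1))
  expect_equal(nrow(b$rows), 8)  # 10 - (E-1)*tau - tp
  expect_equal(ncol(b$rows), 2)
  expect_equal(unname(b$rows[1, ]), c(2, 1))  # x(t), x(t - tau)
  expect_equal(b$targets[1], 3)               # x(t + tp)

  # degenerate E = 1: states are scalars x(t), targets x(t+1)
  b1 <- embed_series(rs, embedding_spec(E = 1, tp = 1))
  expect_equal(unname(b1$rows[, 1]), 1:9)
  expect_equal(b1$targets, 2:10)

  expect_error(embed_series(rs, embedding_spec(E = 10, tp = 1)),
               "insufficient data")
})

test_that("block embedding uses simultaneous species abundances as dimensions", {
  rs <- replicate_series("a", 0:4,
                         cbind(prey = c(5, 6, 7, 8, 9),
                               predator = c(2, 3, 2, 4, 3)),
                         roles = pp_roles)
  b <- embed_series(rs, embedding_spec(E = 2, tp = 1, mode = "block",
                                       target_species = "predator"))
  expect_equal(colnames(b$rows), c("prey", "predator"))
  expect_equal(nrow(b$rows), 4)
  expect_equal(unname(b$rows[2, ]), c(6, 3))
  expect_equal(b$targets, c(3, 2, 4, 3))
})

test_that("simplex handles exact matches and ties by convention", {
  rows <- matrix(c(0, 1, 2, 10), ncol = 1)
  lib <- structure(list(rows = rows, targets = c(5, 7, 9, 11),
                        row_times = 1:4,
                        spec = embedding_spec(1), target_species = "x",
                        replicate_id = "l"), class = "embedded_block")
  q <- lib
  q$rows <- matrix(1, ncol = 1); q$targets <- NA_real_; q$row_times <- 99
  # query coincides with a library state: forecast is that state's target
  f <- simplex_forecast(lib, q, loo = FALSE, n_neighbors = 2)
  expect_equal(f$forecasts, 7)
  # equidistant from two states: equal-weight mean of their targets
  q$rows <- matrix(0.5, ncol = 1)
  f <- simplex_forecast(lib, q, loo = FALSE, n_neighbors = 2)
  expect_equal(f$forecasts, 6)
})

test_that("simplex forecasts match a brute-force oracle on chaotic data", {
  rs <- logistic_series(36)
  lib <- embed_series(rs, embedding_spec(E = 2, tp = 1))
  qrs <- logistic_series(12, x0 = 0.57, id = "q")
  qry <- embed_series(qrs, embedding_spec(E = 2, tp = 1))
  f <- simplex_forecast(lib, qry, loo = FALSE)
  expected <- vapply(seq_len(nrow(qry$rows)), function(i) {
    oracle_simplex(lib$rows, lib$targets, qry$rows[i, ])
  }, numeric(1))
  expect_lt(max(abs(f$forecasts - expected)), 1e-12)
})

test_that("simplex and S-map match brute-force oracles on random instances", {
  set.seed(401)
  for (rep in 1:40) {
    n <- sample(15:50, 1)
    E <- sample(1:3, 1)
    x <- cumsum(stats::rnorm(n))  # random walk gives spread-out states
    rs <- replicate_series("r", 0:(n - 1),
                           matrix(x - min(x), ncol = 1,
                                  dimnames = list(NULL, "x")))
    lib <- embed_series(rs, embedding_spec(E = E, tp = 1))
    m <- nrow(lib$rows)
    qi <- sample(seq_len(m), min(3, m))
    qry <- lib
    qry$rows <- lib$rows[qi, , drop = FALSE]
    qry$targets <- lib$targets[qi]
    qry$row_times <- lib$row_times[qi] + 1000  # force no exclusion overlap
    fs <- simplex_forecast(lib, qry, loo = FALSE)
    th <- sample(c(0, 0.5, 2), 1)
    fm <- smap_forecast(lib, qry, theta = th, loo = FALSE)
    for (j in seq_along(qi)) {
      expect_equal(fs$forecasts[j],
                   oracle_simplex(lib$rows, lib$targets, qry$rows[j, ]),
                   tolerance = 1e-12)
      expect_equal(fm$forecasts[j],
                   oracle_smap(lib$rows, lib$targets, qry$rows[j, ], th),
                   tolerance = 1e-12)
    }
  }
})

test_that("S-map at theta = 0 is the single global least-squares forecast", {
  rs <- logistic_series(40)
  lib <- embed_series(rs, embedding_spec(E = 2, tp = 1))
  qrs <- logistic_series(15, x0 = 0.44, id = "q")
  qry <- embed_series(qrs, embedding_spec(E = 2, tp = 1))
  fit <- smap_forecast(lib, qry, theta = 0, loo = FALSE)
  gls <- stats::lm.fit(cbind(lib$rows, 1), lib$targets)
  pred <- drop(cbind(qry$rows, 1) %*% gls$coefficients)
  expect_lt(max(abs(fit$forecasts - pred)), 1e-10)
  # every query sees the same global regression coefficients
  expect_lt(max(abs(sweep(fit$coefficients, 2,
                          fit$coefficients[1, ]))), 1e-10)
})

test_that("S-map recovers an exact linear map with zero error at any theta", {
  x <- numeric(30); x[1] <- 1
  for (t in 1:29) x[t + 1] <- 0.5 * x[t] + 2
  rs <- replicate_series("lin", 0:29, matrix(x, ncol = 1,
                                             dimnames = list(NULL, "x")))
  lib <- embed_series(rs, embedding_spec(E = 1, tp = 1))
  for (th in c(0, 1, 4)) {
    fit <- smap_forecast(lib, theta = th)
    expect_lt(max(abs(fit$coefficients[, 1] - 0.5)), 1e-7)
    expect_lt(max(abs(fit$coefficients[, "intercept"] - 2)), 1e-6)
    expect_lt(fit$diagnostics$mae, 1e-8)
  }
})

test_that("leave-one-out exclusion equals removing the row by hand", {
  rs <- logistic_series(25)
  lib <- embed_series(rs, embedding_spec(E = 2, tp = 1))
  i <- 7
  qry <- lib
  qry$rows <- lib$rows[i, , drop = FALSE]
  qry$targets <- lib$targets[i]
  qry$row_times <- lib$row_times[i]
  auto <- smap_forecast(lib, qry, theta = 1, loo = TRUE)
  pruned <- lib
  pruned$rows <- lib$rows[-i, , drop = FALSE]
  pruned$targets <- lib$targets[-i]
  pruned$row_times <- lib$row_times[-i]
  manual <- smap_forecast(pruned, qry, theta = 1, loo = FALSE)
  expect_equal(auto$forecasts, manual$forecasts, tolerance = 1e-13)

  simp_auto <- simplex_forecast(lib, qry, loo = TRUE)
  simp_manual <- simplex_forecast(pruned, qry, loo = FALSE)
  expect_equal(simp_auto$forecasts, simp_manual$forecasts, tolerance = 1e-13)
})

test_that("S-map at theta = 0 recovers VAR(1) coefficients", {
  A <- matrix(c(0.7, 0.1, -0.2, 0.6), 2)
  v <- simulate_var1(A, sd = 0.005, n = 500, seed = 11)
  Ahat <- t(vapply(c("x1", "x2"), function(sp) {
    blk <- embed_series(v, embedding_spec(2, 1, 1, "block", sp))
    colMeans(smap_forecast(blk, theta = 0)$coefficients)[1:2]
  }, numeric(2)))
  expect_lt(max(abs(Ahat - A)), 0.05)
})

test_that("embedding dimension selection unfolds a cycle beyond E = 1", {
  t <- seq(0, 8 * pi, length.out = 120)
  rs <- replicate_series("sine", seq_along(t) - 1,
                         matrix(sin(t) + 1.5, ncol = 1,
                                dimnames = list(NULL, "x")))
  sel <- select_E(rs, E_grid = 1:5)
  # a 1-D embedding folds the cycle onto itself (each value has two
  # futures); two or three coordinates resolve it and cut MAE ~50-fold
  expect_true(sel$E %in% 2:3)
  expect_gt(sel$table$mae[sel$table$E == 1],
            20 * sel$table$mae[sel$table$E == sel$E])
  expect_equal(nrow(sel$table), 5)
})

test_that("E selection is deterministic and total on featureless series", {
  set.seed(7)
  rs <- replicate_series("wn", 0:79,
                         matrix(abs(stats::rnorm(80)) + 1, ncol = 1,
                                dimnames = list(NULL, "x")))
  s1 <- select_E(rs, E_grid = 1:6)
  s2 <- select_E(rs, E_grid = 1:6)
  expect_identical(s1$E, s2$E)
  expect_equal(s1$table$mae, s2$table$mae)
  # too-long candidates are skipped with a warning, not fatal
  short <- replicate_series("s", 0:9, matrix(stats::runif(10) + 1, ncol = 1))
  expect_warning(sel <- select_E(short, E_grid = c(2, 9)), "skipped")
  expect_equal(sel$E, 2)
})

test_that("theta selection finds linearity and nonlinearity correctly", {
  # exact linear data: localization buys nothing, tie-break picks theta = 0
  x <- numeric(40); x[1] <- 1
  for (t in 1:39) x[t + 1] <- 0.9 * x[t] + 1
  lin <- replicate_series("lin", 0:39, matrix(x, ncol = 1,
                                              dimnames = list(NULL, "x")))
  expect_equal(select_theta(lin, E = 1)$theta, 0)

  # chaotic Ricker data: the best theta is positive
  ric <- simulate_map("ricker", r = 3, sigma = 0, n_steps = 120,
                      x0 = 0.3, burn_in = 10)
  expect_gt(select_theta(ric, E = 1)$theta, 0)

  # a single-value grid is returned as-is
  expect_warning(one <- select_theta(lin, E = 1, theta_grid = 0.5),
                 "does not contain 0")
  expect_equal(one$theta, 0.5)
})

test_that("goodness of fit matches hand arithmetic and its invariants", {
  d <- goodness_of_fit(c(1, 2, 3), c(1, 2, 5))
  expect_equal(d$mae, 2 / 3)
  expect_equal(d$mse, 4 / 3)
  expect_equal(d$e2, -1)
  expect_equal(d$rmse^2, d$mse, tolerance = 1e-12)

  perfect <- goodness_of_fit(1:5, 1:5)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$e2, 1)

  # predicting the mean scores exactly zero efficiency
  obs <- c(2, 4, 9, 1)
  expect_equal(goodness_of_fit(obs, rep(mean(obs), 4))$e2, 0)

  # E2 is shift invariant and never exceeds 1; MAE <= RMSE
  set.seed(5)
  for (i in 1:20) {
    o <- stats::rnorm(30); p <- o + stats::rnorm(30, sd = 0.5)
    g <- goodness_of_fit(o, p)
    gs <- goodness_of_fit(o + 100, p + 100)
    expect_lte(g$e2, 1)
    expect_lte(g$mae, g$rmse + 1e-12)
    expect_equal(g$e2, gs$e2, tolerance = 1e-6)
  }

  flat <- goodness_of_fit(rep(2, 4), c(2, 2, 2, 3))
  expect_true(is.na(flat$e2))
  expect_equal(flat$mae, 0.25)
  expect_identical(flat$flags, "e2_undefined")
})
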
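test_that("an unsplit single tree reproduces brute-force empirical quantiles", {
  set.seed(5)
  for (rep in 1:3) {
    y <- round(rnorm(20), 3)
    fr <- field_frame(function(y) 0, y) # outcome column replaced below
    fr$d_y <- y
    fit <- fit_forest(fr, d_y, params = root_only_params(n = 20, seed = rep))
    qs <- c(0.1, 0.25, 0.4, 0.5, 0.6, 0.9)
    pred <- predict_quantiles(fit, tibble::tibble(y = c(-2, 0, 3)), qs)
    oracle <- empirical_quantile_type1(y, qs)
    for (i in 1:3) {
      expect_identical(unname(unlist(pred[i, ])), oracle)
    }
  }
})

test_that("an unsplit tree predicts the training mean everywhere", {
  y <- c(1, 2, 3, 10)
  fr <- field_frame(function(y) 0, seq_along(y))
  fr$d_y <- y
  fit <- fit_forest(fr, d_y, params = root_only_params(n = 4))
  expect_equal(predict_mean(fit, tibble::tibble(y = c(-5, 0, 5))),
               rep(mean(y), 3))
})

test_that("constant outcomes give constant means and quantiles", {
  fr <- field_frame(function(y) 0.0, runif(40, -1, 1))
  fr$d_y <- rep(2.5, 40)
  fit <- fit_forest(fr, d_y, params = fast_params())
  pts <- tibble::tibble(y = c(-0.5, 0, 0.5))
  expect_equal(predict_mean(fit, pts), rep(2.5, 3))
  qm <- predict_quantiles(fit, pts, c(0.1, 0.5, 0.9))
  expect_true(all(as.matrix(qm) == 2.5))
})

test_that("the forest recovers a linear change field", {
  yg <- seq(-1, 1, length.out = 400)
  fr <- field_frame(function(y) -y, yg, noise_sd = 0.02, seed = 2)
  fit <- fit_forest(fr, d_y, params = fast_params(n_trees = 200))
  pts <- tibble::tibble(y = seq(-0.8, 0.8, by = 0.2))
  pred <- predict_mean(fit, pts)
  expect_lt(max(abs(pred + pts$y)), 0.1)
  # monotone decreasing
  expect_true(all(diff(pred) < 0))
})

test_that("quantiles are non-decreasing in q at every query point", {
  ts <- simulate_cusp(300, sd_e = 0.1, seed = 3)
  fr <- make_diff_frame(ts, "y", c("a", "b"))
  fit <- fit_forest(fr, d_y, params = fast_params())
  qs <- seq(0.02, 0.98, by = 0.02)
  qm <- as.matrix(predict_quantiles(fit, fr[1:25, ], qs))
  expect_equal(ncol(qm), 49)
  expect_true(all(apply(qm, 1, function(r) all(diff(r) >= 0))))
  # median bracketed by any straddling pair
  expect_true(all(qm[, "q0.4"] <= qm[, "q0.5"] & qm[, "q0.5"] <= qm[, "q0.6"]))
})

test_that("predictions are deterministic given the seed", {
  ts <- simulate_cusp(200, sd_e = 0.05, seed = 4)
  fr <- make_diff_frame(ts, "y", c("a", "b"))
  f1 <- fit_forest(fr, d_y, params = fast_params(seed = 9))
  f2 <- fit_forest(fr, d_y, params = fast_params(seed = 9))
  pts <- fr[1:10, ]
  expect_identical(predict_mean(f1, pts), predict_mean(f2, pts))
  expect_identical(predict_quantiles(f1, pts, c(0.4, 0.6)),
                   predict_quantiles(f2, pts, c(0.4, 0.6)))
})

test_that("forest quantiles approach nominal coverage on iid data", {
  set.seed(11)
  n <- 2000
  fr <- field_frame(function(y) 0.5 * y, runif(n, -1, 1), noise_sd = 0.3, seed = 11)
  fit <- fit_forest(fr, d_y,
                    params = forest_params(n_trees = 100, min_leaf_size = 20, seed = 1))
  set.seed(12)
  ytest <- runif(n, -1, 1)
  obs <- 0.5 * ytest + rnorm(n, 0, 0.3)
  qm <- predict_quantiles(fit, tibble::tibble(y = ytest), c(0.1, 0.9))
  cov10 <- mean(obs <= qm$q0.1)
  cov90 <- mean(obs <= qm$q0.9)
  expect_lt(abs(cov10 - 0.1), 0.05)
  expect_lt(abs(cov90 - 0.9), 0.05)
})

test_that("invalid quantile requests and inputs are rejected", {
  fr <- field_frame(function(y) -y, seq(-1, 1, length.out = 50))
  fit <- fit_forest(fr, d_y, params = fast_params(n_trees = 10))
  expect_error(predict_quantiles(fit, fr, numeric(0)), "at least one")
  expect_error(predict_quantiles(fit, fr, c(0.6, 0.4)), "increasing")
  expect_error(predict_quantiles(fit, fr, c(0, 0.5)), "strictly in")
  expect_error(predict_mean(fit, tibble::tibble(z = 1)), "predictor")
  expect_error(fit_forest(fr[1:4, ], d_y, params = forest_params(min_leaf_size = 5)),
               "too small")
})

test_that("leaf sizes respect the minimum and glance/tidy report the fit", {
  ts <- simulate_cusp(300, sd_e = 0.05, seed = 6)
  fr <- make_diff_frame(ts, "y", c("a", "b"))
  fit <- fit_forest(fr, d_y,
                    params = forest_params(n_trees = 20, min_leaf_size = 7,
                                           resample = FALSE, seed = 1))
  # every terminal node observed among training rows holds >= 7 of them
  counts <- apply(fit$tn_train, 2, table)
  expect_true(all(unlist(counts) >= 7))
  g <- glance(fit)
  expect_equal(g$n, nrow(fr))
  expect_equal(g$n_trees, 20)
  td <- tidy(fit)
  expect_setequal(td$term, c("y", "a", "b"))
})
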
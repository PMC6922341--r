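test_that("grids enumerate inclusive endpoints and Cartesian products", {
  expect_equal(build_grid(x = c(0, 1, 0.5))$x, c(0, 0.5, 1))
  g <- build_grid(x = c(0, 2, 1), y = c(0, 3, 1))
  expect_equal(nrow(g), 12)
  expect_equal(sort(unique(g$x)), 0:2)
  # floating-point-safe enumeration: 0.1 steps land exactly on 0.7
  g2 <- build_grid(x = c(-1, 1, 0.1))
  expect_equal(nrow(g2), 21)
  expect_true(0.7 %in% g2$x)
  expect_error(build_grid(x = c(1, 0, 0.1)), "min")
  expect_error(build_grid(c(0, 1, 0.1)), "named")
})

test_that("the default cusp grid has 41 x 21 x 21 = 18081 points", {
  g <- cusp_grid()
  expect_equal(nrow(g), 18081)
  expect_equal(length(unique(g$y)), 41)
  expect_equal(length(unique(g$a)), 21)
  expect_equal(length(unique(g$b)), 21)
})

test_that("set points of a linear contraction cluster around its fixed point", {
  fr <- field_frame(function(y) -y, seq(-1, 1, length.out = 2000),
                    noise_sd = 0.1, seed = 3)
  fit <- fit_forest(fr, d_y, params = fast_params(n_trees = 200))
  g <- build_grid(y = c(-1, 1, 0.05))
  sp <- find_setpoints(fit, g, 0.4, 0.6)
  expect_gt(nrow(sp), 0)
  expect_true(any(abs(sp$y) < 1e-9))
  expect_true(all(abs(sp$y) <= 0.3))
  expect_true(all(sp$d_y_lo <= 0 & sp$d_y_hi >= 0))
})

test_that("a strictly positive outcome yields no set points", {
  fr <- field_frame(function(y) 0, runif(60, -1, 1))
  fr$d_y <- rep(0.2, 60)
  fit <- fit_forest(fr, d_y, params = fast_params(n_trees = 20))
  sp <- find_setpoints(fit, build_grid(y = c(-1, 1, 0.1)), 0.4, 0.6)
  expect_equal(nrow(sp), 0)
})

test_that("points flagged at a narrow pair are flagged at any wider pair", {
  ts <- simulate_cusp(400, sd_e = 0.05, seed = 5)
  fr <- make_diff_frame(ts, "y", c("a", "b"))
  fit <- fit_forest(fr, d_y, params = fast_params())
  g <- build_grid(y = c(-1, 1, 0.1), a = c(-0.5, 0.5, 0.25), b = c(-0.5, 0.5, 0.25))
  narrow <- find_setpoints(fit, g, 0.4, 0.6)
  wide <- find_setpoints(fit, g, 0.2, 0.8)
  key <- function(d) paste(d$y, d$a, d$b)
  expect_true(all(key(narrow) %in% key(wide)))
})

test_that("quantile order is validated", {
  fr <- field_frame(function(y) -y, seq(-1, 1, length.out = 50))
  fit <- fit_forest(fr, d_y, params = fast_params(n_trees = 10))
  g <- build_grid(y = c(-1, 1, 0.5))
  expect_error(find_setpoints(fit, g, 0.6, 0.4), "below 0.5")
})

test_that("the default sweep uses the 24 even-quantile pairs", {
  p <- default_quantile_pairs()
  expect_equal(nrow(p), 24)
  expect_equal(p$q_low, seq(0.02, 0.48, by = 0.02))
  expect_equal(p$q_high, 1 - p$q_low)
})

test_that("sweep support counts are coherent with single-pair flags", {
  fr <- field_frame(function(y) -y, seq(-1, 1, length.out = 300),
                    noise_sd = 0.05, seed = 7)
  fit <- fit_forest(fr, d_y, params = fast_params())
  g <- build_grid(y = c(-1, 1, 0.1))
  sw <- quantile_sweep(fit, g)
  expect_equal(nrow(sw), nrow(g))
  expect_true(all(sw$support_count >= 0 & sw$support_count <= 24))
  # support at the fixed point should dominate the basin edges
  expect_gt(sw$support_count[sw$y == 0], sw$support_count[sw$y == 1])
  expect_gt(sw$support_count[sw$y == 0], sw$support_count[sw$y == -1])
  # a coordinate flagged by (0.4, 0.6) contributes to support at wider pairs:
  # support of every coordinate flagged at the narrowest pair must be K
  narrowest <- find_setpoints(fit, g, 0.48, 0.52)
  if (nrow(narrowest) > 0) {
    expect_true(all(sw$support_count[sw$y %in% narrowest$y] == 24))
  }
})

test_that("support counts shrink as pairs narrow toward the median", {
  fr <- field_frame(function(y) -y, seq(-1, 1, length.out = 300),
                    noise_sd = 0.05, seed = 8)
  fit <- fit_forest(fr, d_y, params = fast_params())
  g <- build_grid(y = c(-1, 1, 0.1))
  pairs <- default_quantile_pairs()
  # cumulative support over progressively narrower pair subsets is
  # non-increasing per coordinate
  s_all <- quantile_sweep(fit, g, pairs)$support_count
  s_narrow <- quantile_sweep(fit, g, pairs[13:24, ])$support_count
  expect_true(all(s_narrow <= s_all))
})

test_that("joint set points of two equations are set points of each", {
  fr <- field_frame_2d(matrix(c(-0.5, 0, 0, -0.5), 2), n = 500,
                       noise_sd = 0.05, seed = 9)
  fx <- fit_forest(fr, d_x, params = fast_params())
  fy <- fit_forest(fr, d_y, params = fast_params())
  g <- build_grid(x = c(-1, 1, 0.2), y = c(-1, 1, 0.2))
  joint <- find_setpoints(list(fx, fy), g, 0.4, 0.6)
  only_x <- find_setpoints(fx, g, 0.4, 0.6)
  only_y <- find_setpoints(fy, g, 0.4, 0.6)
  key <- function(d) paste(d$x, d$y)
  expect_true(all(key(joint) %in% key(only_x)))
  expect_true(all(key(joint) %in% key(only_y)))
})
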
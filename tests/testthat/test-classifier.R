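# forests trained on analytic change fields give controlled probe signs
fit_field <- function(f, noise_sd = 0.1, seed = 1, n = 400) {
  fr <- field_frame(f, seq(-1, 1, length.out = n), noise_sd = noise_sd, seed = seed)
  fit_forest(fr, d_y, params = fast_params(n_trees = 200, seed = seed))
}

test_that("probe sign patterns map to attractor, repeller and transient", {
  # clean fields make the probe signs unambiguous: the rule itself is
  # what is under test, so coordinates are supplied directly
  coords <- tibble::tibble(y = 0)
  contraction <- fit_field(function(y) -y, noise_sd = 0.02)
  cls <- classify_setpoints(contraction, coords, delta = 0.05)
  expect_true(all(c("below_y", "above_y", "class") %in% names(cls)))
  expect_equal(as.character(cls$class), "attractor")
  expect_gt(cls$below_y, 0)
  expect_lt(cls$above_y, 0)

  expansion <- fit_field(function(y) y, noise_sd = 0.02)
  cls2 <- classify_setpoints(expansion, coords, delta = 0.05)
  expect_equal(as.character(cls2$class), "repeller")
  expect_lt(cls2$below_y, 0)
  expect_gt(cls2$above_y, 0)

  # constant positive drift: both probe changes share a sign -> transient
  drift <- fit_field(function(y) 0.3, noise_sd = 0.02)
  cls3 <- classify_setpoints(drift, coords, delta = 0.05)
  expect_equal(as.character(cls3$class), "transient")
  expect_gt(cls3$below_y, 0)
  expect_gt(cls3$above_y, 0)
})

test_that("negating the outcome swaps attractors and repellers", {
  yg <- seq(-1, 1, length.out = 400)
  fr <- field_frame(function(y) -y, yg, noise_sd = 0.1, seed = 4)
  neg <- fr
  neg$d_y <- -neg$d_y
  f1 <- fit_forest(fr, d_y, params = fast_params(n_trees = 200, seed = 5))
  f2 <- fit_forest(neg, d_y, params = fast_params(n_trees = 200, seed = 5))
  coords <- tibble::tibble(y = seq(-0.4, 0.4, by = 0.05))
  cls1 <- classify_setpoints(f1, coords, delta = 0.05)
  cls2 <- classify_setpoints(f2, coords, delta = 0.05)
  # identical trees on negated outcomes predict exactly negated changes
  expect_equal(cls1$below_y, -cls2$below_y, tolerance = 1e-12)
  expect_equal(cls1$above_y, -cls2$above_y, tolerance = 1e-12)
  swap <- c(attractor = "repeller", repeller = "attractor", transient = "transient")
  expect_equal(unname(swap[as.character(cls1$class)]), as.character(cls2$class))
})

test_that("class counts cover all levels and sum to the set-point count", {
  contraction <- fit_field(function(y) -y, noise_sd = 0.02)
  sp <- tibble::tibble(y = seq(-0.5, 0.5, by = 0.05))
  cls <- classify_setpoints(contraction, sp, delta = 0.05)
  counts <- count_by_class(cls)
  expect_setequal(counts$class,
                  c("attractor", "repeller", "transient", "cycle", "unclassified"))
  expect_equal(sum(counts$n), nrow(sp))
  expect_equal(counts$n[counts$class == "repeller"], 0)
  empty <- count_by_class(cls[0, ])
  expect_true(all(empty$n == 0))
})

test_that("probe deltas outside half-to-one grid step warn", {
  contraction <- fit_field(function(y) -y, noise_sd = 0.1)
  g <- build_grid(y = c(-0.2, 0.2, 0.1))
  sp <- g # treat every grid coordinate as a candidate; steps attr carries over
  attr(sp, "steps") <- attr(g, "steps")
  expect_warning(classify_setpoints(contraction, sp, delta = 0.01), "grid step")
  expect_warning(classify_setpoints(contraction, sp, delta = 0.5), "grid step")
})

test_that("jacobian of a linear contraction field is minus the pull rate", {
  J <- matrix(c(-0.5, 0, 0, -0.5), 2)
  fr <- field_frame_2d(J, n = 1500, noise_sd = 0.01, seed = 6)
  fx <- fit_forest(fr, d_x, params = fast_params(n_trees = 200))
  fy <- fit_forest(fr, d_y, params = fast_params(n_trees = 200))
  est <- estimate_jacobian(list(fx, fy), c(x = 0, y = 0), delta = 0.3)
  expect_equal(est$class, "attractor")
  expect_equal(sort(Re(est$eigenvalues)), c(-0.5, -0.5), tolerance = 0.2)
  expect_true(all(abs(Im(est$eigenvalues)) <= 0.1 * max(Mod(est$eigenvalues))))
  td <- tidy(est)
  expect_equal(nrow(td), 2)
})

test_that("jacobian of a rotation field has an imaginary eigenvalue pair", {
  J <- matrix(c(0, 0.3, -0.3, 0), 2) # dx = -0.3 y, dy = 0.3 x
  fr <- field_frame_2d(J, n = 1500, noise_sd = 0.01, seed = 7)
  fx <- fit_forest(fr, d_x, params = fast_params(n_trees = 200))
  fy <- fit_forest(fr, d_y, params = fast_params(n_trees = 200))
  est <- estimate_jacobian(list(fx, fy), c(x = 0, y = 0), delta = 0.3)
  expect_equal(est$class, "cycle")
  expect_equal(sort(abs(Im(est$eigenvalues))), c(0.3, 0.3), tolerance = 0.2)
})

test_that("jacobian of a saddle field has mixed-sign real eigenvalues", {
  J <- matrix(c(0.4, 0, 0, -0.4), 2)
  fr <- field_frame_2d(J, n = 1500, noise_sd = 0.01, seed = 8)
  fx <- fit_forest(fr, d_x, params = fast_params(n_trees = 200))
  fy <- fit_forest(fr, d_y, params = fast_params(n_trees = 200))
  est <- estimate_jacobian(list(fx, fy), c(x = 0, y = 0), delta = 0.3)
  expect_equal(est$class, "saddle")
  ev <- sort(Re(est$eigenvalues))
  expect_equal(ev, c(-0.4, 0.4), tolerance = 0.2)
})

test_that("one-dimensional jacobian sign agrees with the probe label", {
  contraction <- fit_field(function(y) -y, noise_sd = 0.02)
  sp <- tibble::tibble(y = seq(-0.3, 0.3, by = 0.05))
  cls <- classify_setpoints(contraction, sp, delta = 0.05)
  for (i in which(cls$class == "attractor")) {
    est <- estimate_jacobian(contraction, sp[i, "y"], delta = 0.05)
    expect_lt(Re(est$eigenvalues[1]), 0)
  }
})

test_that("the middle branch of a folded cusp repels, the outer branches attract", {
  # fixed B = 0.5 > 0, A drawn near 0: set points at -sqrt(.5), 0, +sqrt(.5)
  set.seed(10)
  n <- 4000
  y <- runif(n, -1.2, 1.2)
  d <- tibble::tibble(y = y, d_y = -y^3 + 0.5 * y + rnorm(n, 0, 0.05))
  attr(d, "modeled") <- "y"; attr(d, "controls") <- character()
  attr(d, "outcomes") <- c(y = "d_y")
  class(d) <- c("diff_frame", class(d))
  fit <- fit_forest(d, d_y,
                    params = forest_params(n_trees = 200, min_leaf_size = 10, seed = 1))
  sp <- find_setpoints(fit, build_grid(y = c(-1, 1, 0.0125)), 0.4, 0.6)
  cls <- suppressWarnings(classify_setpoints(fit, sp, delta = 0.05))
  r <- sqrt(0.5)
  near <- function(v, target) abs(v - target) <= 0.15
  expect_true(any(near(cls$y, -r) & cls$class == "attractor"))
  expect_true(any(near(cls$y, r) & cls$class == "attractor"))
  mid <- cls[near(cls$y, 0), ]
  expect_gt(nrow(mid), 0)
  expect_true(all(mid$class == "repeller"))
})
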
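# Shared fixtures and independent oracles.

# brute-force type-1 (lower order statistic) quantile of equally weighted
# values: the smallest value whose cumulative weight reaches q
empirical_quantile_type1 <- function(x, q) {
  xs <- sort(x)
  n <- length(xs)
  vapply(q, function(qq) xs[min(n, max(1, ceiling(qq * n - 1e-9)))], numeric(1))
}

# frame generated by an analytic 1-D change field dy = f(y) + noise
field_frame <- function(f, y, noise_sd = 0, seed = 1) {
  set.seed(seed)
  d <- tibble::tibble(y = y, d_y = f(y) + rnorm(length(y), 0, noise_sd))
  attr(d, "modeled") <- "y"
  attr(d, "controls") <- character()
  attr(d, "outcomes") <- c(y = "d_y")
  class(d) <- c("diff_frame", class(d))
  d
}

# frame for a 2-D analytic change field: delta = J %*% (x, y) + noise
field_frame_2d <- function(J, n = 400, noise_sd = 0, seed = 1, spread = 1) {
  set.seed(seed)
  x <- runif(n, -spread, spread)
  y <- runif(n, -spread, spread)
  d <- tibble::tibble(
    x = x, y = y,
    d_x = J[1, 1] * x + J[1, 2] * y + rnorm(n, 0, noise_sd),
    d_y = J[2, 1] * x + J[2, 2] * y + rnorm(n, 0, noise_sd))
  attr(d, "modeled") <- c("x", "y")
  attr(d, "controls") <- character()
  attr(d, "outcomes") <- c(x = "d_x", y = "d_y")
  class(d) <- c("diff_frame", class(d))
  d
}

# small forest settings used where statistical accuracy is not the point
fast_params <- function(seed = 1, n_trees = 100) {
  forest_params(n_trees = n_trees, min_leaf_size = 5, seed = seed)
}

# an unsplit single-tree forest sees every training row in its root leaf
root_only_params <- function(n, seed = 1) {
  forest_params(n_trees = 1, min_leaf_size = n, resample = FALSE, seed = seed)
}
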
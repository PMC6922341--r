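#' Simulate a time series from the stochastic cusp-catastrophe map
#'
#' Iterates the difference equation
#' \deqn{Y_{t+1} - Y_t = -Y_t^3 + B_t Y_t + A_t + e_t}
#' where `A` (asymmetry) and `B` (bifurcation) are control parameters and
#' `e_t` is Gaussian perturbation noise with standard deviation `sd_e`.
#' By default `A_t` and `B_t` are redrawn independently from uniform
#' distributions at every time step, so a single long trajectory visits
#' both the uni-stable and the folded (bi-stable) regions of the cusp
#' surface. Either control can instead be held at a constant via
#' `fixed_a` / `fixed_b` to explore a specific slice of the surface.
#'
#' @param n Series length (number of observations), at least 2.
#' @param sd_e Standard deviation of the Gaussian perturbation, `>= 0`.
#' @param a_range,b_range Length-2 numeric intervals from which `A_t`
#'   and `B_t` are drawn uniformly at each step.
#' @param fixed_a,fixed_b Optional constants overriding the uniform draws.
#' @param y0 Initial state. Defaults to 0.
#' @param seed Optional integer seed; identical `seed` and parameters give
#'   a bit-identical series.
#'
#' @return A tibble of class `cusp_series` with columns `t` (0-based time
#'   index), `y`, `a`, `b`, and `e`. The perturbation `e[t]` acts on the
#'   transition from `t` to `t + 1`; the final row has `e = NA` since the
#'   last observation has no outgoing transition. The simulation
#'   parameters are attached as the `config` attribute.
#'
#' @examples
#' ts <- simulate_cusp(1000, sd_e = 0.05, seed = 1)
#' prop_error(ts)
#' @export
simulate_cusp <- function(n, sd_e = 0.05,
                          a_range = c(-0.5, 0.5), b_range = c(-0.5, 0.5),
                          fixed_a = NULL, fixed_b = NULL,
                          y0 = 0, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    abort("`n` must be a single integer >= 2.")
  }
  n <- as.integer(n)
  if (!is.numeric(sd_e) || length(sd_e) != 1 || sd_e < 0) {
    abort("`sd_e` must be a single non-negative number.")
  }
  check_interval <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 2 || x[1] > x[2]) {
      abort(sprintf("`%s` must be a numeric interval c(lower, upper).", nm))
    }
  }
  check_interval(a_range, "a_range")
  check_interval(b_range, "b_range")

  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  a <- if (!is.null(fixed_a)) rep(fixed_a, n) else runif(n, a_range[1], a_range[2])
  b <- if (!is.null(fixed_b)) rep(fixed_b, n) else runif(n, b_range[1], b_range[2])
  e <- if (sd_e > 0) rnorm(n - 1L, 0, sd_e) else rep(0, n - 1L)

  y <- numeric(n)
  y[1] <- y0
  for (t in seq_len(n - 1L)) {
    y[t + 1L] <- y[t] - y[t]^3 + b[t] * y[t] + a[t] + e[t]
    if (!is.finite(y[t + 1L]) || abs(y[t + 1L]) > 1e6) {
      abort(sprintf("cusp map diverged at time step %d (|y| > 1e6).", t + 1L),
            class = "setpointr_divergence")
    }
  }

  out <- tibble(t = seq_len(n) - 1L, y = y, a = a, b = b,
                e = c(e, NA_real_))
  config <- list(n = n, sd_e = sd_e, a_range = a_range, b_range = b_range,
                 fixed_a = fixed_a, fixed_b = fixed_b, y0 = y0, seed = seed)
  attr(out, "config") <- config
  class(out) <- c("cusp_series", class(out))
  out
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Proportion of variability attributable to perturbation noise
#'
#' The ratio of the perturbation standard deviation used to simulate a
#' series to the sample standard deviation of the realized states:
#' `sd_e / sd(y)`. With the default uniform control regime this lands
#' around 0.13, 0.25 and 0.34 for `sd_e` of 0.05, 0.10 and 0.15.
#'
#' @param series A `cusp_series` from [simulate_cusp()].
#' @return A single number in `[0, 1]`.
#' @export
prop_error <- function(series) {
  cfg <- attr(series, "config")
  if (is.null(cfg)) abort("`series` must be a cusp_series with a config attribute.")
  if (nrow(series) < 3) abort("`series` must have at least 3 observations.")
  s <- sd(series$y)
  if (s == 0) abort("undefined noise ratio: series is constant.")
  cfg$sd_e / s
}

#' @export
print.cusp_series <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<cusp_series> n = %d, sd_e = %g\n", cfg$n, cfg$sd_e))
  NextMethod()
}
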
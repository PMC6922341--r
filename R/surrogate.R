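#' Simulate a bivariate series with known topology
#'
#' Generates two-channel time series whose true dynamics are known, for
#' exercising the multi-equation pipeline. Two regimes are available,
#' patterned on the arm/ankle accelerometer traces of stair climbing and
#' walking:
#' * `attract` - a linear point attractor: each channel contracts toward
#'   the center at rate `pull` per step, plus Gaussian noise;
#' * `cycle` - a noisy limit cycle: the radius contracts toward `radius`
#'   at rate `pull` while the phase advances by `angular_step` radians
#'   each step.
#'
#' @param regime `"attract"` or `"cycle"`.
#' @param n Series length.
#' @param center Length-2 numeric center of the dynamics. Defaults to
#'   `c(0, -10)` for `attract` and `c(-10, -10)` for `cycle`.
#' @param radius Cycle radius (cycle regime only).
#' @param pull Contraction rate per step, in (0, 1).
#' @param angular_step Phase advance per step in radians (cycle only).
#' @param noise_sd SD of the additive Gaussian noise on each channel.
#' @param seed Optional integer seed.
#' @return A tibble with columns `t`, `x`, `y` and `activity` (the
#'   regime name), with the configuration attached as attribute
#'   `config`.
#' @export
simulate_surrogate <- function(regime = c("attract", "cycle"), n = 2000,
                               center = NULL, radius = 3, pull = 0.2,
                               angular_step = 0.3, noise_sd = 0.3,
                               seed = NULL) {
  regime <- match.arg(regime)
  if (n < 2) abort("`n` must be >= 2.")
  if (pull <= 0 || pull >= 1) abort("`pull` must lie in (0, 1).")
  if (regime == "cycle" && radius <= 0) abort("`radius` must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (is.null(center)) {
    center <- if (regime == "attract") c(0, -10) else c(-10, -10)
  }
  if (!is.numeric(center) || length(center) != 2) {
    abort("`center` must be a length-2 numeric vector.")
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  x <- numeric(n); y <- numeric(n)
  if (regime == "attract") {
    x[1] <- center[1]; y[1] <- center[2]
    for (t in seq_len(n - 1L)) {
      x[t + 1L] <- x[t] - pull * (x[t] - center[1]) + rnorm(1, 0, noise_sd)
      y[t + 1L] <- y[t] - pull * (y[t] - center[2]) + rnorm(1, 0, noise_sd)
    }
  } else {
    r <- radius; theta <- 0
    x[1] <- center[1] + r; y[1] <- center[2]
    for (t in seq_len(n - 1L)) {
      r <- sqrt((x[t] - center[1])^2 + (y[t] - center[2])^2)
      theta <- atan2(y[t] - center[2], x[t] - center[1])
      r_new <- r + pull * (radius - r)
      theta_new <- theta + angular_step
      x[t + 1L] <- center[1] + r_new * cos(theta_new) + rnorm(1, 0, noise_sd)
      y[t + 1L] <- center[2] + r_new * sin(theta_new) + rnorm(1, 0, noise_sd)
    }
  }
  out <- tibble(t = seq_len(n) - 1L, x = x, y = y, activity = regime)
  attr(out, "config") <- list(regime = regime, n = n, center = center,
                              radius = radius, pull = pull,
                              angular_step = angular_step,
                              noise_sd = noise_sd, seed = seed)
  out
}

#' Ground-truth topology of a surrogate configuration
#'
#' Returns what the pipeline should recover from a series generated by
#' [simulate_surrogate()] with the same configuration: the set-point
#' location, its dynamics class, and the Jacobian eigenvalue signature at
#' the center.
#'
#' For the attract regime the change field is exactly linear,
#' `delta = -pull * (x - center)`, so the Jacobian is `-pull` times the
#' identity. For the cycle regime the flow near the center combines
#' rotation by `angular_step` with outward radial motion toward the ring,
#' so the eigenvalues form a complex conjugate pair (non-zero imaginary
#' part) - the cycling signature.
#'
#' @inheritParams simulate_surrogate
#' @return A list with `center`, `class` (`"attractor"` or `"cycle"`),
#'   `eigenvalues` (exact for `attract`, `NULL` for `cycle`) and
#'   `eigen_signature` (`"real_negative"` or `"complex"`).
#' @export
expected_topology <- function(regime = c("attract", "cycle"),
                              center = NULL, radius = 3, pull = 0.2,
                              angular_step = 0.3) {
  regime <- match.arg(regime)
  if (is.null(center)) {
    center <- if (regime == "attract") c(0, -10) else c(-10, -10)
  }
  if (regime == "attract") {
    list(center = center, class = "attractor",
         eigenvalues = c(-pull, -pull),
         eigen_signature = "real_negative")
  } else {
    list(center = center, class = "cycle",
         eigenvalues = NULL,
         eigen_signature = "complex")
  }
}
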
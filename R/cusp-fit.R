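#' Stationary points of the cusp potential
#'
#' Real roots of `alpha + beta * y - y^3 = 0`, the points where the
#' deterministic cusp map predicts zero change. Solved in closed form
#' (trigonometric method for three real roots, Cardano otherwise).
#'
#' @param alpha,beta Scalar control values.
#' @return Sorted numeric vector of one or three real roots.
#' @export
cusp_stationary_points <- function(alpha, beta) {
  # depressed cubic y^3 + p y + q = 0 with p = -beta, q = -alpha
  p <- -beta
  q <- -alpha
  disc <- -4 * p^3 - 27 * q^2
  if (disc > 0) {
    # three distinct real roots
    m <- 2 * sqrt(-p / 3)
    theta <- acos(pmin(1, pmax(-1, 3 * q / (p * m)))) / 3
    roots <- m * cos(theta - 2 * pi * (0:2) / 3)
  } else if (p == 0 && q == 0) {
    roots <- 0
  } else {
    # one real root (counting the multiple-root boundary as one/two)
    sq <- sqrt(pmax(0, q^2 / 4 + p^3 / 27))
    u <- cbrt(-q / 2 + sq)
    v <- cbrt(-q / 2 - sq)
    roots <- u + v
    if (disc == 0 && (p != 0 || q != 0)) {
      roots <- c(roots, -roots / 2) # double root at -r/2
    }
  }
  sort(unique(roots))
}

cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

#' Modes of the cusp equilibrium density
#'
#' The local maxima of `f(y | alpha, beta)`: stationary points where the
#' curvature `beta - 3 y^2` of the log-density is negative. With three
#' stationary points the outer two are modes and the middle one is the
#' antimode separating them.
#'
#' @inheritParams cusp_stationary_points
#' @return Numeric vector of one or two modes.
#' @export
cusp_modes <- function(alpha, beta) {
  r <- cusp_stationary_points(alpha, beta)
  curv <- beta - 3 * r^2
  m <- r[curv < 0]
  if (length(m) == 0) r[which.min(curv)] else m
}

# shared quadrature grid: symmetric, trapezoidal, extended until the
# unnormalized density at the boundary is negligible for all rows
cusp_quad_grid <- function(alpha, beta, half_width = 6, h = 0.02) {
  repeat {
    g_end <- max(abs(alpha)) * half_width + max(c(beta, 0)) * half_width^2 / 2 -
      half_width^4 / 4
    if (g_end < log(1e-10) || half_width > 60) break
    half_width <- half_width + 2
  }
  seq(-half_width, half_width, by = h)
}

# log normalizing constants, E[Z] and E[Z^2] for rows of (alpha, beta)
cusp_moments <- function(alpha, beta, z) {
  cusp_moments_cpp(as.numeric(alpha), as.numeric(beta), as.numeric(z))
}

#' Cusp equilibrium density
#'
#' The stationary density of the stochastic cusp,
#' `f(y | alpha, beta) = psi(alpha, beta) exp(alpha y + beta y^2 / 2 - y^4 / 4)`,
#' with the normalizing constant `psi` computed by trapezoidal quadrature
#' on a range wide enough that the omitted tail mass is below 1e-10.
#'
#' @param y Numeric vector of evaluation points.
#' @param alpha,beta Scalar control values.
#' @return Density values at `y`.
#' @export
dcusp <- function(y, alpha, beta) {
  z <- cusp_quad_grid(alpha, beta)
  mom <- cusp_moments(alpha, beta, z)
  exp(mom$log_psi + alpha * y + beta * y^2 / 2 - y^4 / 4)
}

#' Draw from the cusp equilibrium density by rejection sampling
#'
#' One draw per `(alpha, beta)` pair (recycled against `n`), using a
#' uniform envelope scaled to the density maximum, which sits at one of
#' the stationary points.
#'
#' @param n Number of draws.
#' @param alpha,beta Control values, scalars or length-`n` vectors.
#' @param seed Optional integer seed.
#' @param half_width Envelope support half-width.
#' @return Numeric vector of length `n`.
#' @export
rcusp <- function(n, alpha, beta, seed = NULL, half_width = 4) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  alpha <- rep_len(alpha, n)
  beta <- rep_len(beta, n)
  g <- function(z, a, b) a * z + b * z^2 / 2 - z^4 / 4
  gmax <- vapply(seq_len(n), function(i) {
    r <- cusp_stationary_points(alpha[i], beta[i])
    max(g(r, alpha[i], beta[i]))
  }, numeric(1))
  out <- rep(NA_real_, n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    cand <- runif(length(todo), -half_width, half_width)
    acc <- runif(length(todo)) <
      exp(g(cand, alpha[todo], beta[todo]) - gmax[todo])
    out[todo[acc]] <- cand[acc]
    todo <- todo[!acc]
  }
  out
}

#' Linear multiple R-squared of set-point coordinates
#'
#' Ordinary least-squares fit of the state coordinate on the control
#' coordinates. On set points extracted from a folded (bi-stable) system
#' this plane ignores the fold, so its R-squared lower-bounds what the
#' cusp-aware fit can achieve; on raw simulated series it is essentially
#' zero.
#'
#' @param points Data frame of coordinates.
#' @param y,controls Column names of the state and control coordinates.
#' @return The multiple R-squared.
#' @export
linear_r2 <- function(points, y = "y", controls = c("a", "b")) {
  cols <- c(y, controls)
  if (!all(cols %in% names(points))) {
    abort(sprintf("`points` must contain columns: %s", paste(cols, collapse = ", ")))
  }
  if (nrow(points) < length(cols) + 1) abort("too few points for a linear fit.")
  X <- as.matrix(points[controls])
  if (qr(cbind(1, X))$rank < ncol(X) + 1) abort("rank-deficient design.")
  fit <- lm(stats::reformulate(controls, response = y), data = points)
  summary(fit)$r.squared
}

#' Maximum-likelihood fit of the cusp equilibrium density
#'
#' Fits the stochastic-cusp equilibrium density to observed
#' `(Y, A, B)` triples with the linear structure
#' `alpha_i = a0 + a1 A_i`, `beta_i = b0 + b1 B_i` and a linear state
#' transformation `z_i = w0 + w1 y_i`, maximizing
#' `sum_i log( |w1| psi(alpha_i, beta_i) exp(alpha_i z_i + beta_i z_i^2/2 - z_i^4/4) )`
#' over `(a0, a1, b0, b1, w0, w1)`. The free state scale lets the quartic
#' potential express genuine bimodality regardless of the measurement
#' units of `Y`; without it the fit degenerates to a unimodal density
#' whenever `Y` has small range. In `(alpha, beta)` the density is an
#' exponential family, so the score reduces to moment differences and
#' BFGS with the analytic gradient converges quickly. Several
#' deterministic starts guard against local optima; the best candidate
#' is returned with a convergence flag.
#'
#' @param points Data frame with state and control columns.
#' @param y,a,b Column names.
#' @param starts Optional list of numeric start vectors
#'   `c(a0, a1, b0, b1, w0, w1)`.
#' @param maxit BFGS iteration cap per start.
#' @return An object of class `cusp_fit` with fields `alpha_coefs`
#'   `(a0, a1)`, `beta_coefs` `(b0, b1)`, `w_coefs` `(w0, w1)`,
#'   `loglik`, `converged`, `n`.
#' @export
fit_cusp_mle <- function(points, y = "y", a = "a", b = "b",
                         starts = NULL, maxit = 300) {
  cols <- c(y, a, b)
  if (!all(cols %in% names(points))) {
    abort(sprintf("`points` must contain columns: %s", paste(cols, collapse = ", ")))
  }
  if (nrow(points) < 10) abort("at least 10 points are required.")
  yv <- points[[y]]; av <- points[[a]]; bv <- points[[b]]
  if (var(yv) == 0) {
    return(structure(list(alpha_coefs = c(a0 = NA_real_, a1 = NA_real_),
                          beta_coefs = c(b0 = NA_real_, b1 = NA_real_),
                          w_coefs = c(w0 = NA_real_, w1 = NA_real_),
                          loglik = NA_real_, converged = FALSE,
                          n = length(yv)),
                     class = "cusp_fit"))
  }

  # cache the quadrature moments of the most recent parameter vector so
  # that optim's separate fn/gr calls do not recompute them
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  eval_at <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$val)
    alpha <- par[1] + par[2] * av
    beta <- par[3] + par[4] * bv
    zv <- par[5] + par[6] * yv
    # a coarser grid than dcusp's: quadrature error here only perturbs the
    # optimizer's surface by ~1e-4, well below the statistical noise
    zq <- cusp_quad_grid(alpha, beta, h = 0.04)
    mom <- cusp_moments(alpha, beta, zq)
    val <- list(alpha = alpha, beta = beta, zv = zv, mom = mom)
    cache$par <- par
    cache$val <- val
    val
  }
  nll <- function(par) {
    if (abs(par[6]) < 1e-8) return(1e10)
    e <- eval_at(par)
    ll <- sum(log(abs(par[6])) + e$mom$log_psi +
                e$alpha * e$zv + e$beta * e$zv^2 / 2 - e$zv^4 / 4)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  ngr <- function(par) {
    if (abs(par[6]) < 1e-8) return(rep(0, 6))
    e <- eval_at(par)
    dz <- e$zv - e$mom$ey
    dz2 <- (e$zv^2 - e$mom$ey2) / 2
    gprime <- e$alpha + e$beta * e$zv - e$zv^3
    g <- c(sum(dz), sum(av * dz), sum(dz2), sum(bv * dz2),
           sum(gprime), sum(1 / par[6] + gprime * yv))
    if (!all(is.finite(g))) return(rep(0, 6))
    -g
  }

  if (is.null(starts)) {
    s_y <- sd(yv); m_y <- mean(yv)
    starts <- list(c(0, 1, 0, 1, 0, 1))
    for (w1 in c(1 / s_y, 2 / s_y)) {
      w0 <- -m_y * w1
      starts <- c(starts,
                  list(c(0, 1, 0, 1, w0, w1), c(0, 2, 1, 2, w0, w1)))
    }
  }
  # cheap exploratory pass from every start, then polish the best one
  explore <- list()
  for (s in starts) {
    res <- tryCatch(
      optim(s, nll, ngr, method = "BFGS",
            control = list(maxit = 40, reltol = 1e-8)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    explore[[length(explore) + 1L]] <- res
  }
  if (length(explore) == 0) {
    abort("cusp likelihood optimization failed from every start.")
  }
  vals <- vapply(explore, `[[`, numeric(1), "value")
  best <- tryCatch(
    optim(explore[[which.min(vals)]]$par, nll, ngr, method = "BFGS",
          control = list(maxit = maxit, reltol = 1e-9)),
    error = function(e) explore[[which.min(vals)]]
  )
  grad_norm <- sqrt(sum(ngr(best$par)^2))
  structure(list(alpha_coefs = c(a0 = best$par[1], a1 = best$par[2]),
                 beta_coefs = c(b0 = best$par[3], b1 = best$par[4]),
                 w_coefs = c(w0 = best$par[5], w1 = best$par[6]),
                 loglik = -best$value,
                 converged = best$convergence == 0 && grad_norm < 1e-2 * length(yv),
                 n = length(yv)),
            class = "cusp_fit")
}

#' @export
print.cusp_fit <- function(x, ...) {
  cat("<cusp_fit>", if (x$converged) "converged" else "NOT converged", "\n")
  cat(sprintf("  alpha = %.4f + %.4f A\n", x$alpha_coefs[1], x$alpha_coefs[2]))
  cat(sprintf("  beta  = %.4f + %.4f B\n", x$beta_coefs[1], x$beta_coefs[2]))
  cat(sprintf("  state z = %.4f + %.4f Y\n", x$w_coefs[1], x$w_coefs[2]))
  cat(sprintf("  log-likelihood: %.2f (n = %d)\n", x$loglik, x$n))
  invisible(x)
}

#' @export
tidy.cusp_fit <- function(x, ...) {
  tibble(term = c("a0", "a1", "b0", "b1", "w0", "w1"),
         estimate = c(x$alpha_coefs, x$beta_coefs, x$w_coefs))
}

#' @export
glance.cusp_fit <- function(x, ...) {
  tibble(loglik = x$loglik, converged = x$converged, n = x$n)
}

#' Cobb's pseudo-R-squared for a fitted cusp density
#'
#' Residuals are taken to the mode of the fitted conditional density
#' nearest each observation (the delay convention, which combines the
#' sheets above and below the fold), and the statistic is
#' `1 - var(residual) / var(y)`. Values can be negative for badly
#' misspecified fits and are reported as computed.
#'
#' @param points The data frame the fit was (or is to be) evaluated on.
#' @param fit A converged [fit_cusp_mle()] object.
#' @inheritParams fit_cusp_mle
#' @return The pseudo-R-squared.
#' @export
cobb_r2 <- function(points, fit, y = "y", a = "a", b = "b") {
  if (!inherits(fit, "cusp_fit")) abort("`fit` must be a cusp_fit.")
  if (!isTRUE(fit$converged)) abort("`fit` did not converge.")
  yv <- points[[y]]
  alpha <- fit$alpha_coefs[[1]] + fit$alpha_coefs[[2]] * points[[a]]
  beta <- fit$beta_coefs[[1]] + fit$beta_coefs[[2]] * points[[b]]
  w0 <- fit$w_coefs[[1]]; w1 <- fit$w_coefs[[2]]
  zv <- w0 + w1 * yv
  resid_z <- vapply(seq_along(zv), function(i) {
    m <- cusp_modes(alpha[i], beta[i])
    zv[i] - m[which.min(abs(m - zv[i]))]
  }, numeric(1))
  # back to the observed scale: var(resid_y) = var(resid_z) / w1^2
  1 - var(resid_z / w1) / var(yv)
}
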
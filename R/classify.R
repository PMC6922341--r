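#' Classify the local dynamics around set points
#'
#' Probes each set point by predicting the mean change slightly below and
#' above it along each modeled state dimension, holding all other
#' coordinates (including control parameters) at the set-point values.
#' Per dimension the rule is:
#' * attractor - positive change below and negative change above (flow
#'   toward the set point);
#' * repeller - negative below and positive above (flow away);
#' * transient - changes on both sides share a sign (the system slows
#'   down but passes through). A probe predicting exactly zero change is
#'   treated as transient.
#'
#' For multi-equation systems the per-dimension labels are combined:
#' all-attract gives `attractor`, all-repel gives `repeller`, and any mix
#' gives `transient` (a saddle-like point). For two or more dimensions
#' the Jacobian eigenvalue route ([estimate_jacobian()]) is the
#' recommended refinement, since directional probes cannot see rotation.
#'
#' @param models A `qrforest` or list of them, one per modeled equation.
#'   Each model must know its `state` column (set automatically when
#'   fitted on a `diff_frame`).
#' @param setpoints A tibble of set-point coordinates, e.g. from
#'   [find_setpoints()].
#' @param delta Probe offset on the state dimension(s). Sensible values
#'   lie between half and a whole grid step; values outside that band
#'   trigger a warning (when the grid step is known), not an error.
#' @return `setpoints` with added columns `below_<state>`,
#'   `above_<state>` per dimension and a `class` factor.
#' @export
classify_setpoints <- function(models, setpoints, delta = 0.05) {
  models <- as_model_list(models)
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0) {
    abort("`delta` must be a single positive number.")
  }
  steps <- attr(setpoints, "steps")
  if (!is.null(steps)) {
    st <- steps[[1]]
    if (delta < st / 2 - 1e-12 || delta > st + 1e-12) {
      warn(sprintf(paste0("probe delta %g lies outside half-to-one grid step ",
                          "[%g, %g]; classification may leave the basin."),
                   delta, st / 2, st))
    }
  }
  n <- nrow(setpoints)
  states <- vapply(models, function(m) m$state %||% NA_character_, character(1))
  if (anyNA(states)) {
    abort("every model must record its state column (fit on a diff_frame).")
  }
  if (n == 0) {
    out <- setpoints
    for (s in states) {
      out[[paste0("below_", s)]] <- numeric(0)
      out[[paste0("above_", s)]] <- numeric(0)
    }
    out$class <- factor(character(0), levels = dynamics_levels)
    attr(out, "delta") <- delta
    return(out)
  }
  dim_labels <- matrix(NA_character_, n, length(models))
  extra <- list()
  outside <- 0L
  for (k in seq_along(models)) {
    m <- models[[k]]; s <- states[k]
    if (!s %in% names(setpoints)) {
      abort(sprintf("set points lack the state column `%s`.", s))
    }
    below_pts <- setpoints; below_pts[[s]] <- below_pts[[s]] - delta
    above_pts <- setpoints; above_pts[[s]] <- above_pts[[s]] + delta
    rng <- m$ranges[[s]]
    outside <- outside + sum(below_pts[[s]] < rng[1]) + sum(above_pts[[s]] > rng[2])
    below <- predict_mean(m, below_pts)
    above <- predict_mean(m, above_pts)
    dim_labels[, k] <- dplyr::case_when(
      below > 0 & above < 0 ~ "attractor",
      below < 0 & above > 0 ~ "repeller",
      .default = "transient"
    )
    extra[[paste0("below_", s)]] <- below
    extra[[paste0("above_", s)]] <- above
  }
  if (outside > 0) {
    warn(sprintf("%d probe(s) fell outside the training range of a state variable.",
                 outside))
  }
  all_of_label <- function(lab) {
    rowSums(dim_labels == lab) == ncol(dim_labels)
  }
  cls <- rep("transient", n)
  cls[all_of_label("attractor")] <- "attractor"
  cls[all_of_label("repeller")] <- "repeller"
  out <- dplyr::bind_cols(setpoints, as_tibble(extra))
  out$class <- factor(cls, levels = dynamics_levels)
  for (a in c("q_low", "q_high", "steps", "equations")) {
    attr(out, a) <- attr(setpoints, a)
  }
  attr(out, "delta") <- delta
  out
}

#' Count classified set points per dynamics class
#'
#' @param classified Output of [classify_setpoints()].
#' @return A tibble with columns `class` and `n`, covering every class
#'   level (zero counts included); counts sum to the number of set
#'   points.
#' @export
count_by_class <- function(classified) {
  cls <- if (is.data.frame(classified)) classified$class else classified
  cls <- factor(cls, levels = dynamics_levels)
  tab <- table(cls)
  tibble(class = names(tab), n = as.integer(tab))
}

#' Estimate the Jacobian of predicted change at a set point
#'
#' Surrounds the set point with `2d + 1` probe points (the center plus
#' one pair per state dimension at offsets of `+/- delta`), predicts the
#' change in every modeled equation at each probe, and estimates the
#' matrix of partial derivatives by least squares of predicted change on
#' the state offsets. The eigenvalues of that matrix classify the local
#' dynamics: all real parts negative is attracting, all positive
#' repelling, mixed signs a saddle, and a non-negligible imaginary part
#' signals rotation (cycling) around the set point.
#'
#' @param models A `qrforest` or list of them, one per state dimension.
#' @param setpoint A single set-point coordinate: one-row data frame or
#'   named numeric vector covering all predictor columns.
#' @param delta Probe offset (ring spacing).
#' @param n_rings Number of symmetric probe pairs per axis (offsets
#'   `+/- delta, +/- 2 delta, ...`); more rings average out forest
#'   prediction noise in the slopes.
#' @param im_tol Relative threshold for rotation: imaginary parts below
#'   `im_tol` times the spectral radius are treated as numerically real.
#'   Forest-estimated slopes always carry some asymmetry noise, so tiny
#'   complex parts on otherwise real eigenvalues do not signal cycling.
#' @return An object of class `jacobian_estimate`: list with `matrix`
#'   (d x d slopes, rows = equations, columns = state offsets),
#'   `eigenvalues` (complex), and `class`.
#' @export
estimate_jacobian <- function(models, setpoint, delta = 0.05, im_tol = 0.1,
                              n_rings = 2) {
  models <- as_model_list(models)
  if (is.numeric(setpoint) && !is.null(names(setpoint))) {
    setpoint <- as_tibble(as.list(setpoint))
  }
  if (!is.data.frame(setpoint) || nrow(setpoint) != 1) {
    abort("`setpoint` must be a single coordinate (one-row data frame or named vector).")
  }
  if (!is.numeric(n_rings) || n_rings < 1) abort("`n_rings` must be >= 1.")
  states <- vapply(models, function(m) m$state %||% NA_character_, character(1))
  if (anyNA(states)) abort("every model must record its state column.")
  d <- length(models)
  # center plus n_rings symmetric pairs per axis; extra rings average out
  # forest prediction noise in the least-squares slopes
  mults <- as.vector(outer(c(-1, 1), seq_len(n_rings)))
  n_probe <- length(mults) * d + 1L
  probes <- setpoint[rep(1L, n_probe), , drop = FALSE]
  offsets <- matrix(0, n_probe, d, dimnames = list(NULL, states))
  row <- 1L
  for (k in seq_len(d)) {
    for (m_ in mults) {
      row <- row + 1L
      probes[[states[k]]][row] <- probes[[states[k]]][row] + m_ * delta
      offsets[row, k] <- m_ * delta
    }
  }
  X <- cbind(1, offsets)
  qrX <- qr(X)
  if (qrX$rank < d + 1) abort("singular probe design.")
  J <- matrix(NA_real_, d, d, dimnames = list(states, states))
  for (k in seq_len(d)) {
    pred <- predict_mean(models[[k]], probes)
    J[k, ] <- qr.coef(qrX, pred)[-1]
  }
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev); im <- Im(ev)
  im_thresh <- im_tol * max(Mod(ev), 1e-12)
  cls <- if (any(abs(im) > im_thresh)) {
    "cycle"
  } else if (all(re < 0)) {
    "attractor"
  } else if (all(re > 0)) {
    "repeller"
  } else if (any(re < 0) && any(re > 0)) {
    "saddle"
  } else {
    "unclassified"
  }
  structure(list(matrix = J, eigenvalues = ev, class = cls,
                 delta = delta, setpoint = setpoint),
            class = "jacobian_estimate")
}

#' @export
print.jacobian_estimate <- function(x, ...) {
  cat("<jacobian_estimate>", x$class, "\n")
  print(round(x$matrix, 4))
  cat("eigenvalues:", paste(format(x$eigenvalues, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.jacobian_estimate <- function(x, ...) {
  tibble(eigenvalue = seq_along(x$eigenvalues),
         real = Re(x$eigenvalues),
         imaginary = Im(x$eigenvalues),
         modulus = Mod(x$eigenvalues))
}
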
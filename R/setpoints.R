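#' Build an evaluation grid over predictor space
#'
#' Enumerates the Cartesian product of evenly spaced axes, one per
#' predictor. Axis values run from `min` to `max` inclusive in steps of
#' `step`, enumerated as integer multiples of the step to avoid
#' floating-point drift.
#'
#' @param ... Named axis specifications, each a numeric vector
#'   `c(min, max, step)`.
#' @return A tibble with one column per axis and one row per grid point
#'   (product of axis lengths). The axis values and steps are attached as
#'   attributes `axes` and `steps`.
#' @examples
#' nrow(build_grid(y = c(-1, 1, 0.05), a = c(-0.5, 0.5, 0.05), b = c(-0.5, 0.5, 0.05)))
#' @export
build_grid <- function(...) {
  specs <- list(...)
  if (length(specs) == 0) abort("at least one axis specification is required.")
  if (is.null(names(specs)) || any(names(specs) == "")) {
    abort("every axis must be named.")
  }
  axes <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    if (!is.numeric(sp) || length(sp) != 3) {
      abort(sprintf("axis `%s` must be c(min, max, step).", nm))
    }
    if (sp[1] >= sp[2]) abort(sprintf("axis `%s`: min must be < max.", nm))
    if (sp[3] <= 0) abort(sprintf("axis `%s`: step must be > 0.", nm))
    k <- floor((sp[2] - sp[1]) / sp[3] + 1e-6)
    # snap to 10 decimals so accumulated step error cannot move a value
    # off its decimal coordinate (0.05-step grids hit 0.7 exactly)
    round(sp[1] + (0:k) * sp[3], 10)
  })
  names(axes) <- names(specs)
  grid <- as_tibble(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  attr(grid, "axes") <- axes
  attr(grid, "steps") <- vapply(specs, `[`, numeric(1), 3)
  grid
}

#' Default evaluation grid for the cusp system
#'
#' The state axis spans `[-1, 1]` and both control axes span
#' `[-0.5, 0.5]`, all in steps of 0.05, giving 41 x 21 x 21 = 18081
#' candidate coordinates.
#'
#' @param step Grid step shared by all three axes.
#' @return A tibble grid with columns `y`, `a`, `b`.
#' @export
cusp_grid <- function(step = 0.05) {
  build_grid(y = c(-1, 1, step), a = c(-0.5, 0.5, step), b = c(-0.5, 0.5, step))
}

as_model_list <- function(models) {
  if (inherits(models, "qrforest")) models <- list(models)
  if (!is.list(models) || !all(vapply(models, inherits, logical(1), "qrforest"))) {
    abort("`models` must be a qrforest or a list of qrforest objects.")
  }
  nms <- names(models)
  if (is.null(nms)) nms <- rep("", length(models))
  fallback <- vapply(models, function(m) m$outcome, character(1))
  names(models) <- ifelse(nms == "", fallback, nms)
  models
}

#' Flag set points on an evaluation grid
#'
#' A grid coordinate is flagged as a likely set point when, for every
#' supplied model, the pseudo-confidence interval of predicted change
#' spanned by the `q_low` and `q_high` conditional quantiles contains
#' zero (`q_low quantile <= 0 <= q_high quantile`). With several
#' simultaneous equations the interval must contain zero for all of them.
#'
#' @param models A `qrforest` or list of `qrforest` objects (one per
#'   modeled equation).
#' @param grid A grid from [build_grid()] whose columns cover every
#'   model's predictors.
#' @param q_low,q_high Quantile pair straddling the median.
#' @return A tibble of flagged coordinates with, per equation, the
#'   interval bounds `<outcome>_lo` / `<outcome>_hi`. Attributes `q_low`,
#'   `q_high` and `steps` are attached.
#' @export
find_setpoints <- function(models, grid, q_low = 0.4, q_high = 0.6) {
  models <- as_model_list(models)
  if (!(q_low < 0.5 && 0.5 < q_high)) {
    abort("`q_low` must be below 0.5 and `q_high` above it.")
  }
  keep <- rep(TRUE, nrow(grid))
  bounds <- list()
  for (nm in names(models)) {
    qm <- predict_quantiles(models[[nm]], grid, c(q_low, q_high))
    lo <- qm[[1]]; hi <- qm[[2]]
    keep <- keep & (lo <= 0 & 0 <= hi)
    bounds[[paste0(nm, "_lo")]] <- lo
    bounds[[paste0(nm, "_hi")]] <- hi
  }
  out <- dplyr::bind_cols(grid, as_tibble(bounds))[keep, , drop = FALSE]
  attr(out, "q_low") <- q_low
  attr(out, "q_high") <- q_high
  attr(out, "steps") <- attr(grid, "steps")
  attr(out, "equations") <- names(models)
  out
}

#' Default quantile pairs for the multi-range sweep
#'
#' The even-integer quantiles below and above the median paired from the
#' outside in: (0.02, 0.98), (0.04, 0.96), ..., (0.48, 0.52) - 24 pairs.
#'
#' @return A tibble with columns `q_low`, `q_high`.
#' @export
default_quantile_pairs <- function() {
  lo <- seq(0.02, 0.48, by = 0.02)
  tibble(q_low = lo, q_high = 1 - lo)
}

#' Sweep many quantile pairs and count set-point support
#'
#' Repeats the set-point test of [find_setpoints()] across a list of
#' quantile pairs and counts, per grid coordinate, how many pairs flag it
#' (all equations' intervals containing zero). Coordinates supported by
#' many pairs - including narrow ones - are the most credible set points.
#'
#' @inheritParams find_setpoints
#' @param pairs A data frame with columns `q_low`, `q_high`, each pair
#'   straddling 0.5. Defaults to [default_quantile_pairs()].
#' @return The grid tibble with an added `support_count` column
#'   (0..`nrow(pairs)`).
#' @export
quantile_sweep <- function(models, grid, pairs = default_quantile_pairs()) {
  models <- as_model_list(models)
  if (!all(c("q_low", "q_high") %in% names(pairs))) {
    abort("`pairs` must have columns q_low and q_high.")
  }
  if (any(!(pairs$q_low < 0.5 & 0.5 < pairs$q_high))) {
    abort("every pair must straddle 0.5.")
  }
  qs <- sort(unique(c(pairs$q_low, pairs$q_high)))
  support <- rep(nrow(grid), 0L)
  support <- NULL
  for (nm in names(models)) {
    qm <- as.matrix(predict_quantiles(models[[nm]], grid, qs))
    ilo <- match(pairs$q_low, qs)
    ihi <- match(pairs$q_high, qs)
    inc <- (qm[, ilo, drop = FALSE] <= 0) & (qm[, ihi, drop = FALSE] >= 0)
    support <- if (is.null(support)) inc else (support & inc)
  }
  out <- dplyr::bind_cols(grid, tibble(support_count = as.integer(rowSums(support))))
  attr(out, "n_pairs") <- nrow(pairs)
  attr(out, "steps") <- attr(grid, "steps")
  out
}
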
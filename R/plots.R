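# shared palette for dynamics classes (blue attractors, green repellers,
# tan transients)
dynamics_palette <- c(attractor = "blue", repeller = "green",
                      transient = "tan", cycle = "purple",
                      unclassified = "grey60")

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated cusp trajectory
#'
#' @param object A `cusp_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cusp_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time step", y = "Y") +
    ggplot2::theme_minimal()
}

#' Plot classified set points in control-parameter slices
#'
#' Projects the set-point cloud onto the state and asymmetry axes,
#' faceted over bands of the bifurcation axis, with points colored by
#' dynamics class (blue attractors, green repellers, tan transients).
#'
#' @param classified Output of [classify_setpoints()] with columns `y`,
#'   `a`, `b` and `class`.
#' @param n_slices Number of bifurcation bands.
#' @return A ggplot.
#' @export
plot_setpoints <- function(classified, n_slices = 6) {
  stopifnot(all(c("y", "a", "b", "class") %in% names(classified)))
  d <- dplyr::mutate(classified, b_band = cut(.data$b, n_slices))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$y, color = .data$class)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_color_manual(values = dynamics_palette, drop = FALSE) +
    ggplot2::facet_wrap(~b_band) +
    ggplot2::labs(x = "A (asymmetry)", y = "Y", color = "dynamics") +
    ggplot2::theme_minimal()
}

#' Write a 3-D scatter of classified set points to an image file
#'
#' Renders the (A, B, Y) set-point cloud with \pkg{lattice}, colored by
#' dynamics class, and writes it to a PNG file.
#'
#' @param classified Output of [classify_setpoints()].
#' @param file Output PNG path.
#' @param width,height Device size in pixels.
#' @return `file`, invisibly.
#' @export
plot_setpoints_3d <- function(classified, file, width = 800, height = 800) {
  if (!requireNamespace("lattice", quietly = TRUE)) {
    abort("the lattice package is required for 3-D plots.")
  }
  cls <- factor(classified$class, levels = dynamics_levels)
  cols <- dynamics_palette[as.character(cls)]
  grDevices::png(file, width = width, height = height)
  on.exit(grDevices::dev.off())
  present <- levels(droplevels(cls))
  p <- lattice::cloud(y ~ a * b, data = as.data.frame(classified),
                      col = cols, pch = 16, cex = 0.4,
                      xlab = "A", ylab = "B", zlab = "Y",
                      key = if (length(present) > 0) {
                        list(points = list(col = dynamics_palette[present], pch = 16),
                             text = list(present), corner = c(0, 1))
                      })
  print(p)
  invisible(file)
}

#' Heat map of sweep support with a predicted-change vector overlay
#'
#' Tiles the two state axes by the number of quantile pairs flagging each
#' coordinate (darker means more support, i.e. a more credible set
#' point), optionally overlaying arrows of predicted change from the two
#' fitted equations - either at observed data rows (`points`, e.g. one
#' activity's validation rows) or on a thinned grid.
#'
#' @param sweep Output of [quantile_sweep()] for a two-equation system.
#' @param models Optional list of the two `qrforest` models used for the
#'   arrow overlay.
#' @param points Optional data frame of rows at which arrows are drawn;
#'   defaults to a thinned version of the sweep grid.
#' @param arrow_scale Multiplier applied to predicted changes.
#' @param thin Keep every `thin`-th grid coordinate per axis for arrows.
#' @return A ggplot.
#' @export
plot_heatmap_vectors <- function(sweep, models = NULL, points = NULL,
                                 arrow_scale = 1, thin = 4) {
  axes <- setdiff(names(sweep), "support_count")
  if (length(axes) != 2) abort("`sweep` must have exactly two coordinate axes.")
  x <- axes[1]; y <- axes[2]
  p <- ggplot2::ggplot(sweep, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$support_count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "black") +
    ggplot2::labs(fill = "ranges\nincl. zero") +
    ggplot2::theme_minimal()
  if (!is.null(models)) {
    models <- as_model_list(models)
    states <- vapply(models, function(m) m$state, character(1))
    if (!setequal(states, axes)) {
      abort("the models' state variables must match the sweep axes.")
    }
    if (is.null(points)) {
      ux <- sort(unique(sweep[[x]])); uy <- sort(unique(sweep[[y]]))
      keepx <- ux[seq(1, length(ux), by = thin)]
      keepy <- uy[seq(1, length(uy), by = thin)]
      points <- sweep[sweep[[x]] %in% keepx & sweep[[y]] %in% keepy, axes]
    }
    arrows <- as_tibble(points[, axes])
    for (m in models) {
      arrows[[paste0("d_", m$state)]] <- predict_mean(m, points)
    }
    arrows$xend <- arrows[[x]] + arrow_scale * arrows[[paste0("d_", x)]]
    arrows$yend <- arrows[[y]] + arrow_scale * arrows[[paste0("d_", y)]]
    p <- p + ggplot2::geom_segment(
      data = arrows,
      ggplot2::aes(xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "cm")),
      linewidth = 0.25, color = "red3", alpha = 0.7)
  }
  p
}

#' Plot Monte Carlo recovery summaries
#'
#' Mean linear and cusp pseudo-R-squared against series length, one line
#' per noise level and measure.
#'
#' @param object An `eval_report` from [run_monte_carlo()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eval_report <- function(object, ...) {
  d <- tidyr::pivot_longer(
    as_tibble(object)[c("n", "sd_e", "linear_r2_mean", "cusp_r2_mean")],
    cols = c("linear_r2_mean", "cusp_r2_mean"),
    names_to = "measure", values_to = "r_squared")
  d$measure <- ifelse(d$measure == "linear_r2_mean", "linear", "cusp")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$r_squared,
                                  color = factor(.data$sd_e),
                                  linetype = .data$measure)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "series length", y = expression(R^2),
                  color = "noise SD", linetype = "measure") +
    ggplot2::theme_minimal()
}
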
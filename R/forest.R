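#' Quantile regression forest hyperparameters
#'
#' @param n_trees Number of trees in the ensemble.
#' @param min_leaf_size Minimum number of training observations per
#'   terminal node.
#' @param features_per_split Number of candidate predictors tried at each
#'   split, or `"all"`. Defaults to `ceiling(p / 3)` where `p` is the
#'   number of predictors, the usual regression-forest convention.
#' @param resample Whether each tree is grown on a bootstrap resample of
#'   the training rows (with replacement). With `FALSE` every tree sees
#'   the full training set, which makes a single unsplit tree reproduce
#'   plain empirical quantiles exactly.
#' @param seed Integer seed controlling tree growth.
#' @return A list of class `forest_params`.
#' @export
forest_params <- function(n_trees = 500, min_leaf_size = 5,
                          features_per_split = NULL, resample = TRUE,
                          seed = NULL) {
  if (!is.numeric(n_trees) || n_trees < 1) abort("`n_trees` must be >= 1.")
  if (!is.numeric(min_leaf_size) || min_leaf_size < 1) abort("`min_leaf_size` must be >= 1.")
  if (!is.null(features_per_split) && !identical(features_per_split, "all") &&
      (!is.numeric(features_per_split) || features_per_split < 1)) {
    abort('`features_per_split` must be a positive integer or "all".')
  }
  structure(list(n_trees = as.integer(n_trees),
                 min_leaf_size = as.integer(min_leaf_size),
                 features_per_split = features_per_split,
                 resample = isTRUE(resample),
                 seed = seed),
            class = "forest_params")
}

#' Fit a quantile regression forest to a difference outcome
#'
#' Grows an ensemble of regression trees (via \pkg{ranger}) predicting one
#' difference outcome from the current channel values, and retains the
#' terminal-node assignments of all training rows so that arbitrary
#' conditional quantiles can later be extracted from the weighted
#' empirical distribution of training outcomes (Meinshausen-style
#' quantile regression forest).
#'
#' @param train A `diff_frame` (or plain data frame) of training rows.
#' @param outcome Outcome column, as a bare name or string. For a
#'   `diff_frame` this is one of the `d_<channel>` columns.
#' @param params A [forest_params()] object.
#' @param predictors Character vector of predictor columns. Defaults to
#'   the modeled + control channels of a `diff_frame`, otherwise to all
#'   columns except the outcome.
#' @return An object of class `qrforest`.
#' @examples
#' ts <- simulate_cusp(250, sd_e = 0.05, seed = 1)
#' frame <- make_diff_frame(ts, modeled = "y", controls = c("a", "b"))
#' fit <- fit_forest(frame, d_y, params = forest_params(n_trees = 50, seed = 1))
#' @export
fit_forest <- function(train, outcome, params = forest_params(),
                       predictors = NULL) {
  if (!inherits(params, "forest_params")) abort("`params` must come from forest_params().")
  # accept a bare column name, a string literal, or a variable holding one
  out_quo <- rlang::enquo(outcome)
  if (rlang::quo_is_symbol(out_quo) &&
      rlang::as_name(out_quo) %in% names(train)) {
    outcome <- rlang::as_name(out_quo)
  } else {
    outcome <- rlang::eval_tidy(out_quo)
    if (!is.character(outcome) || length(outcome) != 1) {
      abort("`outcome` must name a single column.")
    }
  }
  if (!outcome %in% names(train)) {
    abort(sprintf("outcome column `%s` not found.", outcome))
  }
  outcome_cols <- attr(train, "outcomes")
  if (is.null(predictors)) {
    predictors <- if (!is.null(outcome_cols)) {
      c(attr(train, "modeled"), attr(train, "controls"))
    } else {
      setdiff(names(train), outcome)
    }
  }
  if (length(predictors) == 0) abort("no predictor columns.")
  if (nrow(train) < max(2, params$min_leaf_size)) {
    abort("training frame too small for the requested `min_leaf_size`.")
  }
  p <- length(predictors)
  mtry <- params$features_per_split
  mtry <- if (is.null(mtry)) ceiling(p / 3) else if (identical(mtry, "all")) p else min(p, as.integer(mtry))

  x <- as.data.frame(train)[, predictors, drop = FALSE]
  y <- train[[outcome]]
  if (anyNA(x) || anyNA(y)) abort("training data contain missing values.")

  rng <- ranger::ranger(
    x = x, y = y,
    num.trees = params$n_trees,
    mtry = mtry,
    min.node.size = params$min_leaf_size,
    min.bucket = params$min_leaf_size,
    replace = params$resample,
    sample.fraction = 1,
    importance = "impurity",
    seed = params$seed,
    num.threads = 1
  )
  tn_train <- stats::predict(rng, x, type = "terminalNodes",
                             num.threads = 1)$predictions
  storage.mode(tn_train) <- "integer"

  # state variable paired with this outcome (probed by the classifier)
  state <- NULL
  if (!is.null(outcome_cols)) {
    hit <- names(outcome_cols)[outcome_cols == outcome]
    if (length(hit) == 1) state <- hit
  }

  structure(list(rng = rng,
                 y = y,
                 tn_train = tn_train,
                 outcome = outcome,
                 predictors = predictors,
                 state = state,
                 ranges = lapply(x, range),
                 params = params),
            class = "qrforest")
}

#' @export
print.qrforest <- function(x, ...) {
  cat(sprintf("<qrforest> outcome: %s | predictors: %s\n", x$outcome,
              paste(x$predictors, collapse = ", ")))
  cat(sprintf("  trees: %d, min leaf: %d, OOB R^2: %.3f\n",
              x$params$n_trees, x$params$min_leaf_size, x$rng$r.squared))
  invisible(x)
}

check_points <- function(model, points) {
  missing_cols <- setdiff(model$predictors, names(points))
  if (length(missing_cols) > 0) {
    abort(sprintf("prediction points lack predictor columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  as.data.frame(points)[, model$predictors, drop = FALSE]
}

#' Predict conditional mean change
#'
#' Ensemble-average prediction of the difference outcome at new predictor
#' values.
#'
#' @param model A `qrforest`.
#' @param points Data frame containing all predictor columns.
#' @return Numeric vector, one prediction per row of `points`.
#' @export
predict_mean <- function(model, points) {
  stopifnot(inherits(model, "qrforest"))
  x <- check_points(model, points)
  if (nrow(x) == 0) return(numeric(0))
  as.numeric(stats::predict(model$rng, x, num.threads = 1)$predictions)
}

#' Predict conditional quantiles of change
#'
#' Conditional quantiles of the difference outcome, computed from the
#' weighted empirical distribution of training outcomes that share
#' terminal nodes with the query point, aggregated across trees. The
#' quantile convention is the lower weighted order statistic (type 1):
#' the smallest training outcome whose cumulative weight reaches `q`.
#'
#' @param model A `qrforest`.
#' @param points Data frame containing all predictor columns.
#' @param qs Probabilities in (0, 1), strictly increasing.
#' @return A tibble with one column per quantile (named `q0.4`, ...) and
#'   one row per row of `points`; values are non-decreasing across each
#'   row.
#' @export
predict_quantiles <- function(model, points, qs) {
  stopifnot(inherits(model, "qrforest"))
  if (length(qs) == 0) abort("`qs` must contain at least one probability.")
  if (any(qs <= 0 | qs >= 1)) abort("all `qs` must lie strictly in (0, 1).")
  if (is.unsorted(qs, strictly = TRUE)) abort("`qs` must be strictly increasing.")
  x <- check_points(model, points)
  if (nrow(x) == 0) {
    m <- matrix(numeric(0), 0, length(qs), dimnames = list(NULL, sprintf("q%g", qs)))
    return(as_tibble(m))
  }
  tn_query <- stats::predict(model$rng, x, type = "terminalNodes",
                             num.threads = 1)$predictions
  storage.mode(tn_query) <- "integer"
  m <- qrf_weighted_quantiles(model$tn_train, tn_query, model$y, as.numeric(qs))
  colnames(m) <- sprintf("q%g", qs)
  as_tibble(m)
}

#' @export
glance.qrforest <- function(x, ...) {
  tibble(n = length(x$y),
         n_trees = x$params$n_trees,
         min_leaf_size = x$params$min_leaf_size,
         mtry = x$rng$mtry,
         oob_mse = x$rng$prediction.error,
         oob_r_squared = x$rng$r.squared)
}

#' @export
tidy.qrforest <- function(x, ...) {
  imp <- x$rng$variable.importance
  tibble(term = names(imp), importance = as.numeric(imp))
}

#' Turn a fitted object into a tidy tibble
#'
#' @param x A fitted object.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary
#'
#' @param x A fitted object.
#' @param ... Passed to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")
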
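#' Build a difference-equation regression frame
#'
#' Converts aligned time-series channels into the regression layout of a
#' first-order difference equation: for each modeled channel the outcome
#' is the lead-minus-current difference `Y[t+1] - Y[t]`, and the
#' predictors are the current values of all modeled and control channels.
#' The last observation has no lead and is dropped, so the frame has one
#' row fewer than the input.
#'
#' @param data A data frame of aligned, equal-length channels.
#' @param modeled Character vector of channel names whose differences are
#'   modeled as outcomes.
#' @param controls Character vector of additional channels used as
#'   predictors only (control parameters). Must be disjoint from
#'   `modeled`.
#'
#' @return A tibble of class `diff_frame` with the current values of
#'   `modeled` and `controls` plus one outcome column `d_<channel>` per
#'   modeled channel. Attributes `modeled`, `controls` and `outcomes`
#'   record the roles.
#'
#' @examples
#' make_diff_frame(data.frame(y = c(2, 5, 4)), modeled = "y")
#' @export
make_diff_frame <- function(data, modeled, controls = character()) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (nrow(data) < 2) abort("`data` must have at least 2 rows.")
  if (length(modeled) == 0) abort("at least one modeled channel is required.")
  used <- c(modeled, controls)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("channels not found in `data`: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (length(intersect(modeled, controls)) > 0) {
    abort("`modeled` and `controls` must be disjoint.")
  }
  for (ch in used) {
    if (!is.numeric(data[[ch]])) abort(sprintf("channel `%s` is not numeric.", ch))
    if (anyNA(data[[ch]])) {
      abort(sprintf("channel `%s` contains missing values at rows: %s",
                    ch, paste(utils::head(which(is.na(data[[ch]])), 5), collapse = ", ")))
    }
  }
  n <- nrow(data)
  cur <- as_tibble(data[seq_len(n - 1L), used, drop = FALSE])
  outs <- lapply(modeled, function(ch) diff(data[[ch]]))
  names(outs) <- paste0("d_", modeled)
  out <- dplyr::bind_cols(cur, as_tibble(outs))
  attr(out, "modeled") <- modeled
  attr(out, "controls") <- controls
  attr(out, "outcomes") <- setNames(paste0("d_", modeled), modeled)
  class(out) <- c("diff_frame", class(out))
  out
}

#' Split a difference frame into training and test sets
#'
#' Partitions the rows of a frame into disjoint, exhaustive training and
#' test subsets. The default is a uniform random row split; `"blocked"`
#' keeps the training rows as the initial contiguous block, which avoids
#' temporal leakage between adjacent rows at the cost of training and
#' test sets covering different epochs.
#'
#' @param frame A `diff_frame` (or any data frame).
#' @param fraction Training fraction, strictly between 0 and 1.
#' @param seed Optional integer seed for the random split.
#' @param method `"random"` (default) or `"blocked"`.
#' @return A list with elements `train` and `test`.
#' @export
split_frame <- function(frame, fraction = 0.5, seed = NULL,
                        method = c("random", "blocked")) {
  method <- match.arg(method)
  if (!is.data.frame(frame) || nrow(frame) == 0) abort("`frame` must be a non-empty data frame.")
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1) {
    abort("`fraction` must be strictly between 0 and 1.")
  }
  n <- nrow(frame)
  n_train <- round(fraction * n)
  n_train <- max(1L, min(n - 1L, as.integer(n_train)))
  if (method == "random") {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(restore_rng(old), add = TRUE)
      set.seed(seed)
    }
    idx <- sort(sample.int(n, n_train))
  } else {
    idx <- seq_len(n_train)
  }
  list(train = keep_frame_attrs(frame[idx, , drop = FALSE], frame),
       test = keep_frame_attrs(frame[setdiff(seq_len(n), idx), , drop = FALSE], frame))
}

keep_frame_attrs <- function(x, template) {
  for (a in c("modeled", "controls", "outcomes")) {
    attr(x, a) <- attr(template, a)
  }
  class(x) <- class(template)
  x
}
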
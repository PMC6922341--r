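#' Read a delimited multivariate time series
#'
#' Reads comma-, tab- or whitespace-delimited text with or without a
#' header row (both auto-detected), selecting and naming the channels of
#' interest. Columns may be addressed by name or by 1-based index, which
#' accommodates headerless sensor logs.
#'
#' @param path Path to the file.
#' @param channels Named character or integer vector mapping output
#'   channel names to input columns, e.g. `c(x = 5, y = 14)` or
#'   `c(arm = "acc_arm_y")`. `NULL` keeps all columns.
#' @param activity Optional single column (name or index) holding a
#'   per-row activity label, returned as character column `activity`.
#' @param delim Field delimiter; `NULL` auto-detects comma, tab or
#'   whitespace.
#' @return A tibble with the numeric channels (and optional `activity`),
#'   one row per input row.
#' @export
read_timeseries <- function(path, channels = NULL, activity = NULL,
                            delim = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0) abort("empty file.")
  if (is.null(delim)) {
    delim <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else "ws"
  }
  raw <- if (identical(delim, "ws")) {
    readr::read_table(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                      progress = FALSE)
  } else {
    readr::read_delim(path, delim = delim, col_names = FALSE,
                      col_types = readr::cols(.default = "c"),
                      progress = FALSE, trim_ws = TRUE)
  }
  # header detection: the first row is a header if it has non-numeric
  # cells in columns that are numeric from the second row on (a column
  # that is text throughout, e.g. an activity label, is not evidence)
  r1 <- suppressWarnings(as.numeric(unlist(raw[1, ])))
  r2 <- if (nrow(raw) > 1) suppressWarnings(as.numeric(unlist(raw[2, ]))) else r1
  has_header <- any(is.na(r1) & !is.na(r2))
  if (has_header) {
    hdr <- as.character(unlist(raw[1, ]))
    raw <- raw[-1, , drop = FALSE]
    names(raw) <- make.names(hdr, unique = TRUE)
  }
  resolve <- function(ref, what) {
    if (is.numeric(ref)) {
      if (ref < 1 || ref > ncol(raw)) abort(sprintf("%s index %s out of range.", what, ref))
      as.integer(ref)
    } else {
      i <- match(ref, names(raw))
      if (is.na(i)) abort(sprintf("%s column `%s` not found.", what, ref))
      i
    }
  }
  if (is.null(channels)) {
    channels <- setNames(seq_len(ncol(raw)), names(raw))
    if (!is.null(activity)) channels <- channels[-resolve(activity, "activity")]
  }
  if (is.null(names(channels)) || any(names(channels) == "")) {
    abort("`channels` must be a fully named vector.")
  }
  out <- list()
  for (nm in names(channels)) {
    i <- resolve(channels[[nm]], "channel")
    v <- raw[[i]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "")
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value in channel `%s` at line %d: \"%s\"",
                    nm, bad[1] + has_header, v[bad[1]]))
    }
    out[[nm]] <- num
  }
  out <- as_tibble(out)
  if (!is.null(activity)) {
    out$activity <- as.character(raw[[resolve(activity, "activity")]])
  }
  out
}

#' Write flagged set points to CSV
#'
#' The flagging quantile pair, probe delta and grid steps are preserved
#' in `#`-prefixed comment lines so that [read_setpoints()] restores
#' them.
#'
#' @param setpoints Output of [find_setpoints()] or
#'   [classify_setpoints()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_setpoints <- function(setpoints, path) {
  meta <- c()
  for (a in c("q_low", "q_high", "delta")) {
    v <- attr(setpoints, a)
    if (!is.null(v)) meta <- c(meta, sprintf("# %s: %.17g", a, v))
  }
  steps <- attr(setpoints, "steps")
  if (!is.null(steps)) {
    meta <- c(meta, sprintf("# steps: %s",
                            paste(sprintf("%s=%.17g", names(steps), steps), collapse = " ")))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta) > 0) writeLines(meta, con)
  utils::write.csv(as.data.frame(setpoints), con, row.names = FALSE)
  invisible(path)
}

#' Read set points written by [write_setpoints()]
#'
#' @param path File path.
#' @return A tibble with the stored columns and restored attributes.
#' @export
read_setpoints <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  out <- readr::read_csv(I(paste(body, collapse = "\n")),
                         col_types = readr::cols(), progress = FALSE)
  if ("class" %in% names(out)) out$class <- factor(out$class, levels = dynamics_levels)
  for (a in c("q_low", "q_high", "delta")) {
    m <- grep(sprintf("^# %s:", a), meta, value = TRUE)
    if (length(m) == 1) attr(out, a) <- as.numeric(sub(sprintf("^# %s:", a), "", m))
  }
  m <- grep("^# steps:", meta, value = TRUE)
  if (length(m) == 1) {
    parts <- strsplit(trimws(sub("^# steps:", "", m)), " ")[[1]]
    kv <- strsplit(parts, "=")
    attr(out, "steps") <- setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
                                   vapply(kv, `[`, character(1), 1))
  }
  out
}

#' Compare forest and least-squares fit per equation
#'
#' For each fitted forest, fits the ordinary least-squares baseline (the
#' outcome regressed on the same predictors) on the training rows and
#' reports the R-squared of both methods on the training and, when
#' supplied, validation rows.
#'
#' @param models A `qrforest` or list of them.
#' @param train Training `diff_frame` used to fit the models.
#' @param test Optional validation `diff_frame`.
#' @return A tidy tibble with columns `equation`, `method`
#'   (`least_squares` / `random_forest`), `sample` (`train` / `test`)
#'   and `r_squared`.
#' @export
report_r2_table <- function(models, train, test = NULL) {
  models <- as_model_list(models)
  rows <- list()
  r2_of <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  for (nm in names(models)) {
    m <- models[[nm]]
    form <- stats::reformulate(m$predictors, response = m$outcome)
    ols <- lm(form, data = train)
    sets <- list(train = train)
    if (!is.null(test)) sets$test <- test
    for (sn in names(sets)) {
      d <- sets[[sn]]
      obs <- d[[m$outcome]]
      rows[[length(rows) + 1L]] <- tibble(
        equation = nm, method = "least_squares", sample = sn,
        r_squared = r2_of(obs, predict(ols, newdata = d)))
      rows[[length(rows) + 1L]] <- tibble(
        equation = nm, method = "random_forest", sample = sn,
        r_squared = r2_of(obs, predict_mean(m, d)))
    }
  }
  dplyr::bind_rows(rows)
}
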
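# Sliding-window featurization: overlapping multi-day blocks of the coded
# grid, flattened day-major and scaled to [0, 1], with region labels.

#' Slice a dataset into overlapping multi-day window features
#'
#' Windows of `window_days` consecutive days are taken at a step of
#' `max(1, floor(window_days * (1 - overlap)))` days (default 25-day windows
#' at 50% overlap: step 12), keeping only full windows. Each window is
#' flattened day-major (day 1 slots 1..288, then day 2, ...) and scaled to
#' `[0, 1]` by dividing the integer codes by 119, giving the feature dimension
#' `window_days * 288` (7200 at defaults).
#'
#' @param ds A `behavior_dataset`.
#' @param window_days Window length in days (default 25).
#' @param overlap Fractional overlap between consecutive windows in `[0, 1)`
#'   (default 0.5).
#' @return An object of class `window_set`: list with `features` (numeric
#'   matrix, one row per window), `info` (data.frame with `start_day`,
#'   `end_day`, `label`), `window_days`, `step`.
#' @export
sliding_windows <- function(ds, window_days = 25L, overlap = 0.5) {
  stopifnot(inherits(ds, "behavior_dataset"))
  window_days <- as.integer(window_days)
  if (overlap < 0 || overlap >= 1)
    stop("overlap must lie in [0, 1)", call. = FALSE)
  if (ds$n_days < window_days)
    stop(sprintf("dataset has %d days, shorter than the %d-day window",
                 ds$n_days, window_days), call. = FALSE)
  step <- max(1L, as.integer(floor(window_days * (1 - overlap))))
  starts <- seq.int(1L, ds$n_days - window_days + 1L, by = step)
  ends <- starts + window_days - 1L
  feats <- matrix(0, nrow = length(starts), ncol = window_days * 288L)
  for (k in seq_along(starts)) {
    block <- ds$grid[starts[k]:ends[k], , drop = FALSE]
    feats[k, ] <- as.numeric(t(block)) / 119
  }
  onset <- ds$meta$onset_day
  stable <- ds$meta$stable_day
  labels <- if (identical(ds$meta$change, "normal") || is.null(onset) || is.null(stable)) {
    rep("normal", length(starts))
  } else {
    mapply(label_window, starts, ends,
           MoreArgs = list(onset_day = onset, stable_day = stable))
  }
  structure(list(
    features = feats,
    info = data.frame(start_day = starts, end_day = ends, label = labels,
                      stringsAsFactors = FALSE),
    window_days = window_days, step = step),
    class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d days (D = %d), step %d days\n",
              nrow(x$features), x$window_days, ncol(x$features), x$step))
  print(table(x$info$label))
  invisible(x)
}

#' Region label of one window from its day span
#'
#' A window is `normal` when it ends before the perturbation onset,
#' `abnormal` when it starts at or after the stabilization day, and
#' `prediction` otherwise (it overlaps the gradual-change region). Labels use
#' the span endpoints, not a majority vote, so the prediction region stays
#' pure for lead-time measurement.
#'
#' @param start_day,end_day 1-based day span of the window.
#' @param onset_day,stable_day Region boundaries (defaults 90 and 180).
#' @return One of `"normal"`, `"prediction"`, `"abnormal"`.
#' @export
label_window <- function(start_day, end_day, onset_day = 90L, stable_day = 180L) {
  if (end_day < onset_day) "normal"
  else if (start_day >= stable_day) "abnormal"
  else "prediction"
}

#' Write / read a window set as CSV (one window per row)
#'
#' Columns: `start_day`, `end_day`, `label`, then the feature values.
#'
#' @param ws A `window_set`.
#' @param path CSV path.
#' @return `write_windows` returns `path` invisibly; `read_windows` the
#'   reconstructed `window_set`.
#' @export
write_windows <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  df <- cbind(ws$info, as.data.frame(ws$features))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  feats <- as.matrix(df[, -(1:3), drop = FALSE])
  dimnames(feats) <- NULL
  n_slots <- 288L
  structure(list(
    features = feats,
    info = df[, 1:3],
    window_days = as.integer(ncol(feats) / n_slots),
    step = if (nrow(df) > 1L) df$start_day[2] - df$start_day[1] else NA_integer_),
    class = "window_set")
}
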
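# Confusion-matrix metrics, lead-time of prediction, and the benchmark
# harness: generate abnormal datasets per change combination, run detector
# families under their own protocols, and tabulate metrics per run.

#' Confusion counts from window decisions and region labels
#'
#' Normal-region windows are the negatives, abnormal-region windows the
#' positives; prediction-region windows are excluded here (they feed the
#' lead-time statistic instead).
#'
#' @param decisions Logical vector (`TRUE` = decided abnormal), one per
#'   window.
#' @param labels Character region labels (`"normal"`, `"prediction"`,
#'   `"abnormal"`), same length.
#' @return An object of class `confusion_counts` with fields `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion_counts <- function(decisions, labels) {
  stopifnot(length(decisions) == length(labels))
  keep <- labels %in% c("normal", "abnormal")
  d <- as.logical(decisions)[keep]
  pos <- labels[keep] == "abnormal"
  structure(list(TP = sum(d & pos), FP = sum(d & !pos),
                 TN = sum(!d & !pos), FN = sum(!d & pos)),
            class = "confusion_counts")
}

#' Detection metrics from confusion counts
#'
#' Accuracy, precision, sensitivity, specificity and F1-score:
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`, `precision = TP / (TP + FP)`,
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `F1 = 2 TP / (2 TP + FP + FN)`. A ratio with zero denominator is
#' undefined and reported as `NA`, never as 0.
#'
#' @param counts A `confusion_counts` object or a list/vector with fields
#'   `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric vector with entries `accuracy`, `precision`,
#'   `sensitivity`, `specificity`, `f1`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  if (total == 0)
    stop("all confusion counts are zero: nothing was evaluated", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  c(accuracy = ratio(tp + tn, total),
    precision = ratio(tp, tp + fp),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    f1 = ratio(2 * tp, 2 * tp + fp + fn))
}

#' Lead-time of prediction from a score series
#'
#' Operationalizes the lead-time as the sustained-detection rule: the
#' detection day is the end day of the earliest prediction-region window
#' from which that window and every later prediction-region window are
#' decided abnormal; the lead-time is `stable_day - detection_day` days
#' (how many days before the behavior stabilizes the change was being
#' flagged consistently). If no such window exists the lead-time is 0.
#'
#' @param series A `score_series` (needs `start_day`, `end_day`,
#'   `decision`).
#' @param onset_day,stable_day Region boundaries (defaults 90 and 180).
#' @return List with `days` (integer >= 0) and `detection_day` (day index or
#'   `NA`).
#' @export
compute_lead_time <- function(series, onset_day = 90L, stable_day = 180L) {
  lab <- mapply(label_window, series$start_day, series$end_day,
                MoreArgs = list(onset_day = onset_day, stable_day = stable_day))
  pred <- which(lab == "prediction")
  if (length(pred) == 0)
    stop("score series covers no prediction-region windows", call. = FALSE)
  pred <- pred[order(series$end_day[pred])]
  dec <- series$decision[pred]
  sustained <- rev(cumprod(rev(dec))) == 1
  if (!any(sustained))
    return(list(days = 0L, detection_day = NA_integer_))
  detection_day <- series$end_day[pred[which(sustained)[1]]]
  # a sustained run can start in a window ending after the stable day
  # (windows straddling the boundary); the lead gained is then zero
  list(days = max(0L, as.integer(stable_day - detection_day)),
       detection_day = as.integer(detection_day))
}

#' Ground-truth oracle decisions for a window set
#'
#' Decides every non-normal window abnormal; used as the reference detector
#' in evaluation tests (attains perfect metrics and the maximal lead-time
#' the window geometry allows).
#'
#' @param ws A `window_set`.
#' @return A `score_series`.
#' @export
oracle_series <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  dec <- ws$info$label != "normal"
  .score_series(ws$info, as.numeric(dec), dec)
}

# ---------------------------------------------------------------------------
# Experiment harness

.EXPERIMENT_KEYS <- c("changes", "replicates", "detectors", "seed", "n_days",
                      "window_days", "overlap", "calibration_days", "jitter",
                      "model_config", "detector_params", "supervised_cap")

#' Configure a change-detection benchmark
#'
#' @param changes List of change-type vectors (each of length 1 or 2) or
#'   `change_spec`s; default all 21 combinations.
#' @param replicates Independent dataset instances per change combination.
#' @param detectors Character vector of detector families to run.
#' @param seed Master seed; every dataset and detector seed derives from it.
#' @param n_days Days per dataset (default 365).
#' @param window_days,overlap Featurization parameters (defaults 25 and 0.5).
#' @param calibration_days Calibration period of the unsupervised families.
#' @param jitter Perturbation-schedule jitter half-width.
#' @param model_config Passed to [make_default_model()].
#' @param detector_params Named list (by family) of hyperparameter overrides.
#' @param supervised_cap Maximum number of pooled training windows for the
#'   supervised families.
#' @return A validated config list of class `experiment_config`.
#' @export
experiment_config <- function(changes = NULL, replicates = 3L,
                              detectors = c("svm", "ocsvm", "sae", "km"),
                              seed = 1L, n_days = 365L, window_days = 25L,
                              overlap = 0.5, calibration_days = 60L,
                              jitter = 0.05, model_config = list(),
                              detector_params = list(),
                              supervised_cap = 240L) {
  if (is.null(changes)) changes <- list_change_combinations()
  changes <- lapply(changes, function(ch)
    if (inherits(ch, "change_spec")) ch else change_spec(ch))
  stopifnot(replicates >= 1, all(detectors %in% .FAMILIES))
  bad <- setdiff(names(detector_params), .FAMILIES)
  if (length(bad) > 0)
    stop("detector_params for unknown families: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(changes = changes, replicates = as.integer(replicates),
                 detectors = detectors, seed = as.integer(seed),
                 n_days = as.integer(n_days),
                 window_days = as.integer(window_days), overlap = overlap,
                 calibration_days = as.integer(calibration_days),
                 jitter = jitter, model_config = model_config,
                 detector_params = detector_params,
                 supervised_cap = as.integer(supervised_cap)),
            class = "experiment_config")
}

.change_name <- function(spec) paste(spec$types, collapse = "")

.make_detector_spec <- function(family, config, seed) {
  extra <- config$detector_params[[family]] %||% list()
  if (family %in% c("km", "dc") && is.null(extra$calibration_days))
    extra$calibration_days <- config$calibration_days
  do.call(detector_spec, c(list(family = family, seed = seed), extra))
}

#' Run the change-detection benchmark
#'
#' Generates `replicates` abnormal datasets for every change combination,
#' featurizes them with overlapping windows, and evaluates each requested
#' detector family under its own protocol: supervised families are trained
#' on labelled windows pooled from *other* dataset instances (per-replicate
#' folds, emulating training data from different subjects); semi-supervised
#' families are trained on the normal-region windows of the dataset under
#' test; unsupervised families consume the whole window stream after their
#' calibration period. Confusion metrics are computed over the normal and
#' abnormal regions; prediction-region windows feed the lead-time statistic.
#'
#' @param config An `experiment_config`.
#' @param out_dir Optional directory: writes `results.csv` (per run) and
#'   `summary.csv` / `summary.json` (aggregates).
#' @param progress Print one line per dataset?
#' @return List with `runs` (one row per change x replicate x family:
#'   metrics and lead-time) and `summary` (mean and sd per change x family).
#' @export
run_experiment <- function(config, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  model <- make_default_model(config$model_config)
  n_ch <- length(config$changes)
  n_rep <- config$replicates

  # generate all datasets and window sets up front
  grids <- vector("list", n_ch * n_rep)
  idx <- function(i, r) (i - 1L) * n_rep + r
  for (i in seq_len(n_ch)) for (r in seq_len(n_rep)) {
    ds_seed <- config$seed + (i - 1L) * 1000L + r
    sched <- perturbation_schedule(jitter = config$jitter, seed = ds_seed)
    ds <- generate_abnormal_dataset(model, config$changes[[i]], sched,
                                    n_days = config$n_days, seed = ds_seed)
    grids[[idx(i, r)]] <- sliding_windows(ds, config$window_days, config$overlap)
    if (progress)
      message(sprintf("dataset %s replicate %d: %d windows",
                      .change_name(config$changes[[i]]), r,
                      nrow(grids[[idx(i, r)]]$features)))
  }

  # supervised folds: the fit used on test dataset (i, r) never saw windows
  # of that instance -- with several replicates, folds pool the *other*
  # replicates across all changes; with one replicate, they pool the other
  # changes' datasets
  sup_fams <- intersect(config$detectors, c("svm", "cnn"))
  n_folds <- if (n_rep > 1L) n_rep else n_ch
  sup_fits <- list()
  for (fam in sup_fams) {
    sup_fits[[fam]] <- vector("list", n_folds)
    for (r in seq_len(n_folds)) {
      pool_ids <- if (n_rep > 1L) {
        unlist(lapply(seq_len(n_ch), function(i)
          vapply(setdiff(seq_len(n_rep), r), function(rr) idx(i, rr), integer(1))))
      } else {
        setdiff(seq_len(n_ch), r)
      }
      if (length(pool_ids) == 0L)
        stop("supervised detection needs at least two dataset instances", call. = FALSE)
      feats <- do.call(rbind, lapply(pool_ids, function(g)
        grids[[g]]$features[grids[[g]]$info$label != "prediction", , drop = FALSE]))
      labs <- unlist(lapply(pool_ids, function(g) {
        l <- grids[[g]]$info$label
        l[l != "prediction"] == "abnormal"
      }))
      set.seed(config$seed + r)
      if (nrow(feats) > config$supervised_cap) {
        keep <- sample.int(nrow(feats), config$supervised_cap)
        if (length(unique(labs[keep])) < 2L)
          keep <- c(keep, which(labs != labs[keep[1]])[1])
        feats <- feats[keep, , drop = FALSE]; labs <- labs[keep]
      }
      ws_train <- grids[[1]] # geometry template for cnn reshape
      ws_train$features <- feats
      ws_train$info <- data.frame(start_day = NA_integer_, end_day = NA_integer_,
                                  label = NA_character_)[rep(1, nrow(feats)), ]
      spec <- .make_detector_spec(fam, config, config$seed + r)
      sup_fits[[fam]][[r]] <- fit_supervised(spec, ws_train, labels = labs)
    }
  }

  rows <- list()
  for (i in seq_len(n_ch)) for (r in seq_len(n_rep)) {
    ws <- grids[[idx(i, r)]]
    for (fam in config$detectors) {
      det_seed <- config$seed + (i - 1L) * 100L + r * 7L
      series <- if (fam %in% c("svm", "cnn")) {
        fold <- if (n_rep > 1L) r else i
        score(sup_fits[[fam]][[fold]], ws)
      } else if (fam %in% c("ocsvm", "sae")) {
        det <- fit_semisupervised(.make_detector_spec(fam, config, det_seed), ws)
        score(det, ws)
      } else {
        fit_predict_unsupervised(.make_detector_spec(fam, config, det_seed), ws)
      }
      m <- compute_metrics(confusion_counts(series$decision, ws$info$label))
      lt <- compute_lead_time(series)
      rows[[length(rows) + 1L]] <- data.frame(
        change = .change_name(config$changes[[i]]), family = fam,
        replicate = r, t(m), lead_time_days = lt$days,
        stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, rows)
  summary <- aggregate_results(runs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(runs, file.path(out_dir, "results.csv"), row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(runs = runs, summary = summary)
}

#' Aggregate per-run benchmark rows (mean and sd over replicates)
#'
#' @param runs The `runs` data.frame of [run_experiment()].
#' @return Data.frame with one row per change x family and `<metric>_mean` /
#'   `<metric>_sd` columns.
#' @export
aggregate_results <- function(runs) {
  metrics <- c("accuracy", "precision", "sensitivity", "specificity", "f1",
               "lead_time_days")
  groups <- unique(runs[, c("change", "family")])
  out <- lapply(seq_len(nrow(groups)), function(g) {
    sel <- runs$change == groups$change[g] & runs$family == groups$family[g]
    row <- data.frame(change = groups$change[g], family = groups$family[g],
                      n = sum(sel), stringsAsFactors = FALSE)
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(runs[[m]][sel], na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- stats::sd(runs[[m]][sel])
    }
    row
  })
  do.call(rbind, out)
}
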
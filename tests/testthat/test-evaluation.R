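test_that("confusion counting scores positives/negatives and skips prediction windows", {
  lab <- c("normal", "normal", "prediction", "abnormal", "abnormal", "abnormal")
  dec <- c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  cc <- confusion_counts(dec, lab)
  expect_equal(cc$TP, 2); expect_equal(cc$FP, 1)
  expect_equal(cc$TN, 1); expect_equal(cc$FN, 1)
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 5) # prediction window excluded
})

test_that("metric formulas reproduce hand-computed and brute-force values", {
  # perfect case
  m <- compute_metrics(list(TP = 1, FP = 0, TN = 1, FN = 0))
  expect_true(all(m == 1))
  # direct substitution: F1 = 2*2 / (2*2 + 1 + 1) = 4/6
  m <- compute_metrics(list(TP = 2, FP = 1, TN = 0, FN = 1))
  expect_equal(m[["f1"]], 4 / 6)
  expect_equal(m[["accuracy"]], 0.5)
  # zero-denominator ratios are NA, others still computed
  m <- compute_metrics(list(TP = 0, FP = 0, TN = 3, FN = 2))
  expect_true(is.na(m[["precision"]]))
  expect_equal(m[["specificity"]], 1)
  expect_equal(m[["sensitivity"]], 0)
  expect_error(compute_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)), "zero")

  # lattice of small integer counts vs the independent implementation
  for (tp in 0:3) for (fp in 0:3) for (tn in 0:3) for (fn in 0:3) {
    if (tp + fp + tn + fn == 0) next
    expect_equal(compute_metrics(list(TP = tp, FP = fp, TN = tn, FN = fn)),
                 brute_force_metrics(tp, fp, tn, fn))
  }
})

test_that("metric identities hold on integer counts", {
  set.seed(5)
  for (i in 1:25) {
    c4 <- as.list(stats::setNames(sample(0:20, 4, replace = TRUE),
                                  c("TP", "FP", "TN", "FN")))
    if (Reduce(`+`, c4) == 0) next
    m <- compute_metrics(c4)
    n <- Reduce(`+`, c4)
    if (!is.na(m[["sensitivity"]]))
      expect_equal(m[["sensitivity"]] * (c4$TP + c4$FN), c4$TP)
    if (!is.na(m[["sensitivity"]]) && !is.na(m[["specificity"]]))
      expect_equal(m[["accuracy"]],
                   m[["sensitivity"]] * (c4$TP + c4$FN) / n +
                   m[["specificity"]] * (c4$TN + c4$FP) / n)
  }
})

series_from <- function(ends, decisions, window = 25L) {
  structure(data.frame(start_day = ends - window + 1L, end_day = ends,
                       score = as.numeric(decisions), decision = decisions,
                       calibration = FALSE),
            class = c("score_series", "data.frame"))
}

test_that("lead-time follows the sustained-detection rule", {
  ends <- seq(25L, 361L, by = 12L) # default 25-day windows on 365 days
  pred_ends <- ends[ends >= 90 & (ends - 24) < 180]

  # all prediction windows abnormal: lead from the earliest prediction end
  s <- series_from(ends, ends >= 90)
  lt <- compute_lead_time(s)
  expect_equal(lt$detection_day, min(pred_ends))
  expect_equal(lt$days, 180L - min(pred_ends))

  # nothing detected: zero lead
  s0 <- series_from(ends, rep(FALSE, length(ends)))
  expect_equal(compute_lead_time(s0)$days, 0L)

  # sustained detection only from a mid-region day on
  ends2 <- c(97L, 120L, 150L, 171L)
  s2 <- series_from(ends2, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(compute_lead_time(s2)$detection_day, 150L)
  expect_equal(compute_lead_time(s2)$days, 30L)
  # an interrupted run does not count
  s3 <- series_from(ends2, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(compute_lead_time(s3)$days, 30L)

  expect_error(compute_lead_time(series_from(c(25L, 50L), c(TRUE, TRUE))),
               "prediction-region")
})

test_that("turning any prediction decision abnormal never lowers the lead-time", {
  ends <- seq(25L, 361L, by = 12L)
  set.seed(17)
  for (trial in 1:100) {
    dec <- stats::runif(length(ends)) < 0.4
    base <- compute_lead_time(series_from(ends, dec))$days
    flip <- sample(which(ends >= 90 & (ends - 24) < 180), 1)
    dec2 <- dec; dec2[flip] <- TRUE
    expect_gte(compute_lead_time(series_from(ends, dec2))$days, base)
  }
})

test_that("the ground-truth oracle attains perfect metrics and maximal lead", {
  grid <- matrix(sample(0:119, 365 * 288, replace = TRUE), 365, 288)
  ds <- behavior_dataset(grid, meta = list(change = "St", onset_day = 90,
                                           stable_day = 180))
  ws <- sliding_windows(ds)
  s <- oracle_series(ws)
  m <- compute_metrics(confusion_counts(s$decision, ws$info$label))
  expect_true(all(m == 1))
  lt <- compute_lead_time(s)
  pred_ends <- ws$info$end_day[ws$info$label == "prediction"]
  expect_equal(lt$days, 180L - min(pred_ends))
  expect_lte(lt$days, 90L)
})

test_that("a coin-flip detector sits at one-half accuracy", {
  set.seed(23)
  lab <- rep(c("normal", "abnormal"), 600)
  dec <- stats::runif(1200) < 0.5
  m <- compute_metrics(confusion_counts(dec, lab))
  expect_lt(abs(m[["accuracy"]] - 0.5), 3 * sqrt(0.25 / 1200))
})

test_that("experiment configs are validated before any computation", {
  expect_error(experiment_config(detectors = "bogus"))
  expect_error(experiment_config(detector_params = list(bogus = list())),
               "unknown families")
  cfg <- experiment_config(changes = list("Di", c("St", "Lo")), replicates = 2)
  expect_length(cfg$changes, 2)
  expect_s3_class(cfg$changes[[2]], "change_spec")
})

test_that("a small benchmark produces consistent per-run and aggregate tables", {
  cfg <- experiment_config(changes = list("Di", "Sw"), replicates = 2,
                           detectors = c("ocsvm", "km"), n_days = 250,
                           window_days = 5, seed = 7)
  res <- run_experiment(cfg)
  expect_equal(nrow(res$runs), 2 * 2 * 2) # changes x replicates x families
  expect_true(all(res$runs$f1 >= 0 & res$runs$f1 <= 1, na.rm = TRUE))
  expect_true(all(res$runs$lead_time_days >= 0 & res$runs$lead_time_days <= 90))

  # aggregates match recomputation from the per-run rows
  agg <- aggregate_results(res$runs)
  for (g in seq_len(nrow(agg))) {
    sel <- res$runs$change == agg$change[g] & res$runs$family == agg$family[g]
    expect_equal(agg$f1_mean[g], mean(res$runs$f1[sel]))
    expect_equal(agg$accuracy_sd[g], stats::sd(res$runs$accuracy[sel]))
  }

  # deterministic under the same config seed
  res2 <- run_experiment(cfg)
  expect_identical(res$runs, res2$runs)
})
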
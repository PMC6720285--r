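test_that("detector specifications validate their hyperparameters", {
  expect_error(detector_spec("nope"), "arg")
  expect_error(detector_spec("svm", bogus = 1), "unknown svm hyperparameters")
  s <- detector_spec("sae", pretrain_epochs = 5, seed = 9)
  expect_equal(s$params$pretrain_epochs, 5)
  expect_equal(s$seed, 9L)
})

test_that("supervised detectors separate labelled clusters perfectly", {
  ws <- synthetic_window_set(n = 30, sep = 3, seed = 21)
  labels <- ws$info$label == "abnormal"

  det <- fit_supervised(detector_spec("svm"), ws, labels)
  s <- score(det, ws)
  expect_equal(s$decision, labels)
  expect_true(det$fit$gamma %in% det$fit$searched)

  det2 <- fit_supervised(detector_spec("cnn", epochs = 15), ws, labels)
  s2 <- score(det2, ws)
  expect_equal(s2$decision, labels)
  # softmax output: probability pairs sum to one
  nn <- asNamespace("behavbench")
  probs <- nn$nn_softmax(nn$nn_forward(det2$fit$net,
                                       nn$.encode_windows(ws, "raw")))
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)

  expect_error(fit_supervised(detector_spec("svm"), ws, rep(TRUE, 30)),
               "semisupervised")
})

test_that("stacked auto-encoder layer widths follow the compression factors", {
  expect_equal(sae_layer_sizes(7200), c(7200L, 900L, 180L, 60L))
  expect_equal(sae_layer_sizes(1440), c(1440L, 180L, 36L, 12L))
})

test_that("reconstruction error separates training windows from shuffled ones", {
  # Monte-Carlo: a window with its slots randomly permuted must score higher
  # than an intact training window, on average over >= 20 trials
  ws <- synthetic_window_set(n = 24, days = 3, slots = 16, sep = 0,
                             noise = 0.2, seed = 31, frac_abnormal = 0)
  ws$features <- ws$features + outer(rep(1, 24), sin(seq_len(48)))
  det <- fit_semisupervised(detector_spec("sae", pretrain_epochs = 30,
                                          finetune_epochs = 60), ws)
  s_train <- score(det, ws)$score
  set.seed(99)
  diffs <- vapply(1:20, function(i) {
    w <- ws$features[sample.int(24, 1), ]
    shuf <- w[sample.int(length(w))]
    wsp <- ws; wsp$features <- rbind(w, shuf)
    wsp$info <- wsp$info[c(1, 2), ]
    sc <- score(det, wsp)$score
    sc[2] - sc[1]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_lt(mean(s_train), det$threshold)
})

test_that("the one-class SVM honours its nu training-error bound", {
  # soft-margin contract: training outliers never exceed the support-vector
  # count, and approach the nu fraction as n grows
  set.seed(41)
  X <- matrix(stats::runif(300 * 48, 0.2, 0.8), 300, 48)
  det <- fit_semisupervised(detector_spec("ocsvm", nu = 0.1), X)
  s <- score(det, X)
  expect_lte(mean(s$decision), det$fit$model$tot.nSV / nrow(X))
  expect_lte(mean(s$decision), 0.1 + 3 * sqrt(0.1 * 0.9 / nrow(X)))
  expect_error(fit_semisupervised(detector_spec("sae"), X[1, , drop = FALSE]),
               "at least two")
})

test_that("unsupervised detection honours calibration and flags the shifted regime", {
  for (fam in c("km", "dc")) {
    spec <- if (fam == "dc") detector_spec("dc", calibration_days = 40,
                                           epochs = 6, seed = 5)
            else detector_spec("km", calibration_days = 40, seed = 5)
    ws <- synthetic_window_set(n = 50, days = 4, slots = 24, sep = 2.5,
                               seed = 51, frac_abnormal = 0.4)
    series <- fit_predict_unsupervised(spec, ws)
    expect_equal(nrow(series), 50)
    calib <- ws$info$end_day <= 40
    expect_true(all(series$calibration == calib))
    expect_false(any(series$decision[calib]))
    post <- !calib
    lab <- ws$info$label
    expect_gt(mean(series$decision[post & lab == "abnormal"]), 0.9)
    # the 0.95-quantile threshold over ~20 calibration windows is noisy;
    # most post-calibration normal windows must still pass unflagged
    expect_lt(mean(series$decision[post & lab == "normal"]), 0.4)
  }
})

test_that("a constant window stream yields equal scores and no alarms", {
  ws <- synthetic_window_set(n = 30, noise = 0, sep = 0, seed = 61,
                             frac_abnormal = 0)
  series <- fit_predict_unsupervised(detector_spec("km", calibration_days = 30), ws)
  post <- !series$calibration
  expect_true(length(unique(round(series$score[post], 12))) == 1)
  expect_false(any(series$decision))
  expect_error(fit_predict_unsupervised(
    detector_spec("km", calibration_days = 1000), ws), "calibration")
})

test_that("scoring is deterministic, duplicate-consistent and dimension-checked", {
  ws <- synthetic_window_set(n = 30, sep = 2, seed = 71)
  labels <- ws$info$label == "abnormal"
  for (fam in c("svm", "ocsvm", "sae", "cnn")) {
    spec <- switch(fam,
      svm = detector_spec("svm", seed = 2),
      cnn = detector_spec("cnn", epochs = 5, seed = 2),
      ocsvm = detector_spec("ocsvm", seed = 2),
      sae = detector_spec("sae", pretrain_epochs = 10, finetune_epochs = 10,
                          seed = 2))
    ws_norm <- ws
    ws_norm$features <- ws$features[!labels, , drop = FALSE]
    ws_norm$info <- ws$info[!labels, ]
    fit_once <- function() {
      if (fam %in% c("svm", "cnn")) fit_supervised(spec, ws, labels)
      else fit_semisupervised(spec, ws_norm)
    }
    s1 <- score(fit_once(), ws)
    s2 <- score(fit_once(), ws)
    expect_identical(s1$score, s2$score)
    # a duplicated window receives an identical score
    dup <- ws
    dup$features <- ws$features[c(1, 1), ]
    dup$info <- ws$info[c(1, 1), ]
    sd <- score(fit_once(), dup)
    expect_equal(sd$score[1], sd$score[2])
  }
  det <- fit_semisupervised(detector_spec("ocsvm", encoding = "raw"),
                            ws$features[!labels, ])
  expect_error(score(det, ws$features[, 1:10]), "dimension")
})

test_that("unsupervised runs are reproducible under a fixed seed", {
  ws <- synthetic_window_set(n = 40, sep = 2, seed = 81, frac_abnormal = 0.4)
  a <- fit_predict_unsupervised(detector_spec("km", calibration_days = 30, seed = 3), ws)
  b <- fit_predict_unsupervised(detector_spec("km", calibration_days = 30, seed = 3), ws)
  expect_identical(a$score, b$score)
  d1 <- fit_predict_unsupervised(detector_spec("dc", calibration_days = 30,
                                               epochs = 4, seed = 3), ws)
  d2 <- fit_predict_unsupervised(detector_spec("dc", calibration_days = 30,
                                               epochs = 4, seed = 3), ws)
  expect_identical(d1$score, d2$score)
})

test_that("one-class detection beats supervised training on mismatched data", {
  # the supervised detector learns abnormal = centered at -mu from other
  # "subjects", while the monitored stream drifts to +mu: its decision rule
  # transfers badly, whereas one-class training on the stream's own normal
  # windows does not care; asserted as a tendency over >= 10 seeds
  f1 <- function(dec, lab) {
    m <- compute_metrics(confusion_counts(dec, lab))
    ifelse(is.na(m["f1"]), 0, m["f1"])
  }
  res <- t(vapply(1:10, function(s) {
    test_ws <- synthetic_window_set(n = 40, sep = 1.5, seed = 100 + s,
                                    frac_abnormal = 0.5)
    train_ws <- synthetic_window_set(n = 40, sep = -1.5, seed = 200 + s,
                                     frac_abnormal = 0.5)
    sup <- fit_supervised(detector_spec("svm", seed = s), train_ws,
                          train_ws$info$label == "abnormal")
    norm_ws <- test_ws
    keep <- test_ws$info$label == "normal"
    norm_ws$features <- test_ws$features[keep, , drop = FALSE]
    norm_ws$info <- test_ws$info[keep, ]
    semi <- fit_semisupervised(detector_spec("ocsvm", seed = s), norm_ws)
    lab <- test_ws$info$label
    c(sup = f1(score(sup, test_ws)$decision, lab),
      semi = f1(score(semi, test_ws)$decision, lab))
  }, c(sup = 0, semi = 0)))
  expect_gt(mean(res[, "semi"]), mean(res[, "sup"]))
})
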
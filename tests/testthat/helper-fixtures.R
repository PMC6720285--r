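# Fixtures built in code: degenerate models and synthetic window sets.

# One-sub-model model with an absorbing Tired state that deterministically
# emits sleeping-in-bedroom at very low heart rate, starting at midnight.
degenerate_model <- function(code_label = "AS_BR_VL") {
  parts <- strsplit(code_label, "_")[[1]]
  code <- encode_triple(parts[1], parts[2], parts[3])
  emis <- matrix(0, 3, 120)
  emis[, code + 1] <- 1
  make_default_model(list(
    n_submodels = 1,
    submodels = list(list(
      start_mean = 0, start_sd = 1e-3,
      init = c(T = 1, H = 0, E = 0),
      trans = matrix(c(1, 0, 0, 1, 0, 0, 1, 0, 0), 3, 3, byrow = TRUE),
      emis = emis,
      dur_mean = c(T = 60, H = 60, E = 60),
      dur_sd = c(T = 10, H = 10, E = 10)))))
}

# Synthetic window set: two Gaussian blobs in a (days x slots) geometry,
# ordered in time with the normal blob first.
synthetic_window_set <- function(n = 40, days = 4, slots = 24, sep = 2,
                                 noise = 0.3, seed = 1, frac_abnormal = 0.5) {
  set.seed(seed)
  n_ab <- round(n * frac_abnormal)
  X <- matrix(stats::rnorm(n * days * slots, 0, noise), n)
  lab <- c(rep("normal", n - n_ab), rep("abnormal", n_ab))
  X[lab == "abnormal", ] <- X[lab == "abnormal", ] + sep
  starts <- seq(1, by = 2, length.out = n)
  structure(list(
    features = X,
    info = data.frame(start_day = starts, end_day = starts + days - 1,
                      label = lab, stringsAsFactors = FALSE),
    window_days = days, step = 2), class = "window_set")
}

# Independent brute-force metrics: expand counts to label/decision vectors
# and tabulate directly.
brute_force_metrics <- function(tp, fp, tn, fn) {
  truth <- c(rep(TRUE, tp), rep(TRUE, fn), rep(FALSE, tn), rep(FALSE, fp))
  decided <- c(rep(TRUE, tp), rep(FALSE, fn), rep(FALSE, tn), rep(TRUE, fp))
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  c(accuracy = rat(sum(truth == decided), length(truth)),
    precision = rat(sum(truth & decided), sum(decided)),
    sensitivity = rat(sum(truth & decided), sum(truth)),
    specificity = rat(sum(!truth & !decided), sum(!truth)),
    f1 = rat(2 * sum(truth & decided),
             2 * sum(truth & decided) + sum(!truth & decided) + sum(truth & !decided)))
}

# Exhaustive optimal 2-means over all bipartitions (for <= 14 points).
brute_force_2means <- function(X) {
  n <- nrow(X)
  best <- NULL; best_ss <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    ss <- 0
    for (g in c(TRUE, FALSE)) {
      pts <- X[grp == g, , drop = FALSE]
      ss <- ss + sum(sweep(pts, 2, colMeans(pts))^2)
    }
    if (ss < best_ss) { best_ss <- ss; best <- grp }
  }
  list(partition = best, ss = best_ss)
}
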
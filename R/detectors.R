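# Six interchangeable anomaly detectors over window features:
#   supervised      svm (RBF kernel, grid-searched scale), cnn (small convnet)
#   semi-supervised ocsvm (one-class SVM), sae (stacked auto-encoder,
#                   reconstruction-error score)
#   unsupervised    km (weighted K-means, anomalous-cluster init),
#                   dc (deep clustering: convolutional auto-encoder + 2-means
#                   in latent space)
# Score orientation is uniform: higher = more abnormal.

.FAMILIES <- c("svm", "cnn", "ocsvm", "sae", "km", "dc")

.detector_defaults <- function(family) {
  switch(family,
    svm = list(cost = 1, gamma_grid = NULL, cv_folds = 5L, subsample = 150L,
               encoding = "slotfreq"),
    cnn = list(channels = c(4L, 4L, 8L, 8L), fc = 32L, epochs = 10L,
               batch = 16L, lr = 1e-3, threshold = 0.5),
    ocsvm = list(nu = 0.1, gamma = NULL, encoding = "slotfreq"),
    sae = list(compression = c(8, 5, 3), pretrain_epochs = 50L,
               finetune_epochs = 120L, batch = 16L, lr = 1e-3,
               threshold_q = 0.95),
    km = list(k = 2L, beta = 2, threshold_q = 0.95, calibration_days = 60L,
              max_iter = 50L, weight_clamp = 4, encoding = "slotfreq"),
    dc = list(channels = c(4L, 8L, 8L), kernels = c(5L, 5L, 3L), latent = 10L,
              epochs = 10L, batch = 16L, lr = 1e-3, k = 2L,
              threshold_q = 0.95, calibration_days = 60L))
}

#' Specify an anomaly detector
#'
#' @param family One of `"svm"`, `"cnn"` (supervised), `"ocsvm"`, `"sae"`
#'   (semi-supervised), `"km"`, `"dc"` (unsupervised).
#' @param ... Family-specific hyperparameter overrides. Defaults: `svm` --
#'   RBF kernel, `cost = 1`, kernel scale grid-searched by cross-validation
#'   on subsampled training data; `cnn` -- four 3x3 convolutional layers,
#'   two 2x2 max-pool subsampling layers, two fully connected layers with a
#'   two-unit softmax output; `ocsvm` -- `nu = 0.1`; `sae` -- hidden layers
#'   compressed 8x / 5x / 3x from the input (7200 -> 900 -> 180 -> 60 at the
#'   default feature dimension), reconstruction-error score thresholded at
#'   the 0.95 training quantile; `km` -- weighted 2-means with
#'   anomalous-cluster initialization, 60-day calibration; `dc` --
#'   convolutional auto-encoder (kernel sizes 5, 5, 3, mirrored decoder)
#'   with 2-means in the latent space.
#' @param seed Integer seed used by every stochastic step of the family.
#' @return An object of class `detector_spec`.
#' @export
detector_spec <- function(family = .FAMILIES, ..., seed = 1L) {
  family <- match.arg(family)
  defaults <- .detector_defaults(family)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0)
    stop("unknown ", family, " hyperparameters: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(family = family,
                 params = utils::modifyList(defaults, overrides),
                 seed = as.integer(seed)),
            class = "detector_spec")
}

#' @export
print.detector_spec <- function(x, ...) {
  cat(sprintf("<detector_spec> %s (seed %d)\n", x$family, x$seed))
  invisible(x)
}

.win_features <- function(windows) {
  if (inherits(windows, "window_set")) windows$features else as.matrix(windows)
}

# Internal window re-encoding for the kernel / distance detector families
# ("slotfreq"): per 5-minute slot, the frequency of each component symbol
# across the window's days, scaled by the symbol's positional weight in the
# combined code (ADL 20/119, LOC 5/119, HRL 1/119). This averages day-level
# sampling noise while preserving the intensity geometry of the combined
# code, in which location- and heart-rate-only changes span a narrower
# value range than activity-level changes. Raw matrices (no window
# structure) pass through unchanged.
.slotfreq_encode <- function(X, window_days, n_slots = 288L) {
  wts <- c(20, 5, 1) / 119
  codes <- pmin(pmax(round(X * 119), 0L), 119L)
  n <- nrow(X)
  out <- matrix(0, n, n_slots * 15L)
  rows <- rep(seq_len(n), n_slots)
  base <- rep((seq_len(n_slots) - 1L) * 15L, each = n)
  for (dd in seq_len(window_days)) {
    cd <- codes[, (dd - 1L) * n_slots + seq_len(n_slots), drop = FALSE]
    comp <- list(cd %/% 20L, 6L + (cd %/% 5L) %% 4L, 10L + cd %% 5L)
    for (k in 1:3) {
      ii <- cbind(rows, base + as.vector(comp[[k]]) + 1L)
      out[ii] <- out[ii] + wts[k]
    }
  }
  out / window_days
}

# Apply a detector family's internal encoding to a window container.
.encode_windows <- function(windows, encoding) {
  X <- .win_features(windows)
  if (identical(encoding, "slotfreq") && inherits(windows, "window_set"))
    X <- .slotfreq_encode(X, windows$window_days,
                          ncol(X) %/% windows$window_days)
  X
}

.win_info <- function(windows) {
  if (inherits(windows, "window_set")) return(windows$info)
  n <- nrow(as.matrix(windows))
  data.frame(start_day = rep(NA_integer_, n), end_day = rep(NA_integer_, n),
             label = rep(NA_character_, n), stringsAsFactors = FALSE)
}

.win_shape <- function(windows) {
  if (inherits(windows, "window_set"))
    c(windows$window_days, ncol(windows$features) / windows$window_days)
  else
    stop("this detector needs a window_set (to reshape windows into day x slot grids)",
         call. = FALSE)
}

.score_series <- function(info, score, decision, calibration = FALSE) {
  structure(data.frame(start_day = info$start_day, end_day = info$end_day,
                       score = as.numeric(score),
                       decision = as.logical(decision),
                       calibration = calibration,
                       stringsAsFactors = FALSE),
            class = c("score_series", "data.frame"))
}

# Median heuristic for the RBF kernel scale: gamma such that a typical
# squared inter-point distance maps to exp(-1). Computed on a subsample.
.rbf_gamma0 <- function(X, max_n = 120L) {
  n <- nrow(X)
  if (n > max_n) X <- X[round(seq(1, n, length.out = max_n)), , drop = FALSE]
  d2 <- stats::dist(X)^2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med <= 0) 1 / ncol(X) else 1 / med
}

# -- supervised --------------------------------------------------------------

#' Fit a supervised detector (svm or cnn) on labelled windows
#'
#' @param spec A `detector_spec` with family `"svm"` or `"cnn"`.
#' @param windows A `window_set` or numeric feature matrix.
#' @param labels Logical vector (`TRUE` = abnormal). If `NULL` and `windows`
#'   is a labelled `window_set`, labels are taken from the region labels
#'   (prediction-region windows are dropped from training).
#' @return A `trained_detector`.
#' @export
fit_supervised <- function(spec, windows, labels = NULL) {
  stopifnot(inherits(spec, "detector_spec"))
  if (!spec$family %in% c("svm", "cnn"))
    stop("fit_supervised expects family svm or cnn", call. = FALSE)
  encoding <- if (spec$family == "svm") spec$params$encoding else "raw"
  X <- .encode_windows(windows, encoding)
  if (is.null(labels)) {
    lab <- .win_info(windows)$label
    keep <- lab %in% c("normal", "abnormal")
    X <- X[keep, , drop = FALSE]
    labels <- lab[keep] == "abnormal"
  }
  labels <- as.logical(labels)
  stopifnot(length(labels) == nrow(X))
  if (length(unique(labels)) < 2L)
    stop("supervised training needs both classes; with normal-only data use fit_semisupervised",
         call. = FALSE)
  p <- spec$params
  fit <- if (spec$family == "svm") {
    set.seed(spec$seed)
    grid <- p$gamma_grid %||% (2^(-2:2) * .rbf_gamma0(X))
    sub <- if (nrow(X) > p$subsample) {
      i <- sample.int(nrow(X), p$subsample)
      # keep both classes in the subsample
      if (length(unique(labels[i])) < 2L)
        i <- c(i, which(labels != labels[i[1]])[1])
      i
    } else seq_len(nrow(X))
    # abnormal windows outnumber normal ones in pooled training data;
    # inverse-frequency class weights keep the boundary honest
    cw <- c("FALSE" = 1 / mean(!labels), "TRUE" = 1 / mean(labels))
    acc <- vapply(grid, function(g) {
      set.seed(spec$seed)
      m <- e1071::svm(X[sub, , drop = FALSE], factor(labels[sub]),
                      kernel = "radial", gamma = g, cost = p$cost,
                      class.weights = cw, scale = FALSE, cross = p$cv_folds)
      m$tot.accuracy
    }, numeric(1))
    gamma <- grid[which.max(acc)]
    set.seed(spec$seed)
    model <- e1071::svm(X, factor(labels), kernel = "radial", gamma = gamma,
                        cost = p$cost, class.weights = cw, scale = FALSE)
    list(model = model, gamma = gamma, searched = grid)
  } else {
    shape <- .win_shape(windows)
    net <- .cnn_build(shape[1], shape[2], p, spec$seed)
    X4 <- X
    onehot <- cbind(!labels, labels) * 1
    net <- nn_train(net, X4, onehot, loss = "xent", epochs = p$epochs,
                    batch_size = p$batch, lr = p$lr, seed = spec$seed)
    list(net = net, shape = shape)
  }
  structure(list(spec = spec, mode = "supervised", fit = fit,
                 dim = ncol(X), encoding = encoding,
                 threshold = if (spec$family == "cnn") p$threshold else 0),
            class = "trained_detector")
}

.cnn_build <- function(h, w, p, seed) {
  ch <- p$channels
  h1 <- max(1L, h %/% 2L); w1 <- max(1L, w %/% 2L)
  h2 <- max(1L, h1 %/% 2L); w2 <- max(1L, w1 %/% 2L)
  nn_network(list(
    nn_reshape(h, w, 1L),
    nn_conv2d(3L, 3L, 1L, ch[1]), nn_relu(),
    nn_conv2d(3L, 3L, ch[1], ch[2]), nn_relu(),
    nn_maxpool2(),
    nn_conv2d(3L, 3L, ch[2], ch[3]), nn_relu(),
    nn_conv2d(3L, 3L, ch[3], ch[4]), nn_relu(),
    nn_maxpool2(),
    nn_flatten(),
    nn_dense(h2 * w2 * ch[4], p$fc), nn_relu(),
    nn_dense(p$fc, 2L)
  ), seed = seed)
}

# -- semi-supervised ---------------------------------------------------------

#' Layer widths of the stacked auto-encoder for a given input dimension
#'
#' Successive compression factors (default 8, 5, 3) applied to the input
#' dimension: 7200 input units give hidden layers of 900, 180 and 60 units.
#'
#' @param input_dim Feature dimension of the windows.
#' @param compression Compression factor of each successive hidden layer.
#' @return Integer vector `c(input_dim, hidden...)`.
#' @export
sae_layer_sizes <- function(input_dim, compression = c(8, 5, 3)) {
  sizes <- input_dim
  for (f in compression) sizes <- c(sizes, max(2L, round(sizes[length(sizes)] / f)))
  as.integer(sizes)
}

.sae_fit <- function(X, p, seed) {
  sizes <- sae_layer_sizes(ncol(X), p$compression)
  n_hidden <- length(sizes) - 1L
  enc <- vector("list", n_hidden)
  dec <- vector("list", n_hidden)
  rep_in <- X
  # greedy layer-wise pre-training: each layer learned as a shallow AE
  for (i in seq_len(n_hidden)) {
    ae <- nn_network(list(
      nn_dense(sizes[i], sizes[i + 1]), nn_relu(),
      nn_dense(sizes[i + 1], sizes[i])
    ), seed = seed + i)
    ae <- nn_train(ae, rep_in, rep_in, loss = "mse",
                   epochs = p$pretrain_epochs, batch_size = p$batch,
                   lr = p$lr, seed = seed + i)
    enc[[i]] <- ae$layers[[1]]
    dec[[i]] <- ae$layers[[3]]
    rep_in <- nn_forward(nn_network(list(enc[[i]], nn_relu())), rep_in)
  }
  # assemble the full stack and fine-tune end to end
  layers <- list()
  for (i in seq_len(n_hidden)) layers <- c(layers, list(enc[[i]], nn_relu()))
  for (i in rev(seq_len(n_hidden))) {
    layers <- c(layers, list(dec[[i]]))
    if (i > 1L) layers <- c(layers, list(nn_relu()))
  }
  net <- structure(list(layers = layers), class = "nn_network")
  net <- nn_train(net, X, X, loss = "mse", epochs = p$finetune_epochs,
                  batch_size = p$batch, lr = p$lr, seed = seed)
  net
}

.recon_error <- function(net, X) {
  rowMeans((nn_forward(net, X) - X)^2)
}

#' Fit a semi-supervised detector (ocsvm or sae) on normal windows only
#'
#' The one-class SVM fits an RBF decision boundary around the normal
#' windows. The stacked auto-encoder learns to reconstruct normal windows
#' (greedy layer-wise pre-training followed by end-to-end fine-tuning); its
#' anomaly score is the reconstruction error and its decision threshold the
#' `threshold_q` quantile of the training reconstruction errors.
#'
#' @param spec A `detector_spec` with family `"ocsvm"` or `"sae"`.
#' @param windows A `window_set` or feature matrix of normal windows only.
#'   Labelled window sets are filtered to their normal-region windows.
#' @return A `trained_detector`.
#' @export
fit_semisupervised <- function(spec, windows) {
  stopifnot(inherits(spec, "detector_spec"))
  if (!spec$family %in% c("ocsvm", "sae"))
    stop("fit_semisupervised expects family ocsvm or sae", call. = FALSE)
  encoding <- if (spec$family == "ocsvm") spec$params$encoding else "raw"
  X <- .encode_windows(windows, encoding)
  lab <- .win_info(windows)$label
  if (!all(is.na(lab))) X <- X[lab == "normal", , drop = FALSE]
  if (nrow(X) < 2L)
    stop("semi-supervised training needs at least two normal windows", call. = FALSE)
  p <- spec$params
  fit <- if (spec$family == "ocsvm") {
    set.seed(spec$seed)
    gamma <- p$gamma %||% .rbf_gamma0(X)
    model <- e1071::svm(X, y = NULL, type = "one-classification",
                        kernel = "radial", nu = p$nu, gamma = gamma,
                        scale = FALSE)
    list(model = model, gamma = gamma)
  } else {
    net <- .sae_fit(X, p, spec$seed)
    list(net = net, train_errors = .recon_error(net, X))
  }
  threshold <- if (spec$family == "ocsvm") 0
               else unname(stats::quantile(fit$train_errors, p$threshold_q))
  structure(list(spec = spec, mode = "semi-supervised", fit = fit,
                 dim = ncol(X), encoding = encoding, threshold = threshold),
            class = "trained_detector")
}

# -- unsupervised ------------------------------------------------------------

.cae_build <- function(h, w, p, seed) {
  ch <- p$channels; kk <- p$kernels
  h1 <- max(1L, h %/% 2L); w1 <- max(1L, w %/% 2L)
  h2 <- max(1L, h1 %/% 2L); w2 <- max(1L, w1 %/% 2L)
  flat <- h2 * w2 * ch[3]
  encoder <- list(
    nn_reshape(h, w, 1L),
    nn_conv2d(kk[1], kk[1], 1L, ch[1]), nn_relu(),
    nn_maxpool2(),
    nn_conv2d(kk[2], kk[2], ch[1], ch[2]), nn_relu(),
    nn_maxpool2(),
    nn_conv2d(kk[3], kk[3], ch[2], ch[3]), nn_relu(),
    nn_flatten(),
    nn_dense(flat, p$latent)
  )
  decoder <- list(
    nn_dense(p$latent, flat), nn_relu(),
    nn_unflatten(h2, w2, ch[3]),
    nn_conv2d(kk[3], kk[3], ch[3], ch[2]), nn_relu(),
    nn_upsample2(h1, w1),
    nn_conv2d(kk[2], kk[2], ch[2], ch[1]), nn_relu(),
    nn_upsample2(h, w),
    nn_conv2d(kk[1], kk[1], ch[1], 1L)
  )
  list(net = nn_network(c(encoder, decoder), seed = seed),
       n_encoder = length(encoder))
}

.dominant_cluster <- function(cluster, calib) {
  tab <- table(factor(cluster[calib], levels = sort(unique(cluster))))
  as.integer(names(tab)[which.max(tab)])
}

# Normal behavior profile: centroid of the calibration-period windows that
# fell into the dominant cluster. Calibration windows are the only ones the
# detector may treat as normal by construction, so the profile is estimated
# there; the clustering supplies the feature weights / latent geometry and
# screens calibration outliers assigned to the minority cluster.
.normal_profile <- function(X, cluster, dominant, calib) {
  mem <- calib & cluster == dominant
  if (!any(mem)) mem <- calib
  colMeans(X[mem, , drop = FALSE])
}

#' Run an unsupervised detector (km or dc) over a window stream
#'
#' There is no separate training phase: the whole stream is clustered, the
#' cluster holding the majority of the calibration-period windows (default:
#' windows ending within the first 60 days) is taken as the normal profile,
#' and every window is scored by its distance to that profile (weighted
#' feature distance for `km`; Euclidean distance in the convolutional
#' auto-encoder latent space for `dc`). Calibration windows are flagged and
#' always decided normal; later windows are decided abnormal when their
#' score exceeds the `threshold_q` quantile of the calibration scores.
#'
#' @param spec A `detector_spec` with family `"km"` or `"dc"`.
#' @param windows A `window_set` spanning at least the calibration period.
#' @return A `score_series` (one row per window, input order) with a
#'   `detector` attribute holding the fitted state.
#' @export
fit_predict_unsupervised <- function(spec, windows) {
  stopifnot(inherits(spec, "detector_spec"))
  if (!spec$family %in% c("km", "dc"))
    stop("fit_predict_unsupervised expects family km or dc", call. = FALSE)
  if (!inherits(windows, "window_set"))
    stop("unsupervised detection needs a window_set (day spans drive calibration)",
         call. = FALSE)
  X <- windows$features
  info <- windows$info
  p <- spec$params
  calib <- info$end_day <= p$calibration_days
  if (!any(calib))
    stop(sprintf("stream shorter than the %d-day calibration period",
                 p$calibration_days), call. = FALSE)
  if (all(calib))
    stop("stream contains only calibration-period windows", call. = FALSE)
  encoding <- if (spec$family == "km") p$encoding else "raw"
  if (spec$family == "km") {
    Xe <- .encode_windows(windows, encoding)
    wk <- weighted_kmeans(Xe, k = p$k, beta = p$beta, max_iter = p$max_iter,
                          weight_clamp = p$weight_clamp)
    dom <- .dominant_cluster(wk$cluster, calib)
    profile <- .normal_profile(Xe, wk$cluster, dom, calib)
    score <- .wk_dist(Xe, profile, wk$weights^p$beta)
    state <- list(centers = wk$centers, weights = wk$weights, beta = p$beta,
                  dominant = dom, profile = profile)
    enc_dim <- ncol(Xe)
  } else {
    shape <- .win_shape(windows)
    cae <- .cae_build(shape[1], shape[2], p, spec$seed)
    img <- nn_forward(nn_network(list(nn_reshape(shape[1], shape[2], 1L)),
                                 seed = 1L), X)
    net <- nn_train(cae$net, X, img, loss = "mse", epochs = p$epochs,
                    batch_size = p$batch, lr = p$lr, seed = spec$seed)
    encoder <- structure(list(layers = net$layers[seq_len(cae$n_encoder)]),
                         class = "nn_network")
    latent <- nn_forward(encoder, X)
    km <- stats::kmeans(latent, centers = .anomalous_init(latent, p$k),
                        iter.max = 50)
    dom <- .dominant_cluster(km$cluster, calib)
    profile <- .normal_profile(latent, km$cluster, dom, calib)
    score <- rowSums(sweep(latent, 2, profile)^2)
    state <- list(encoder = encoder, centers = km$centers, dominant = dom,
                  profile = profile)
    enc_dim <- ncol(X)
  }
  threshold <- unname(stats::quantile(score[calib], p$threshold_q))
  det <- structure(list(spec = spec, mode = "unsupervised", fit = state,
                        dim = enc_dim, encoding = encoding,
                        threshold = threshold),
                   class = "trained_detector")
  series <- .score_series(info, score, score > threshold & !calib,
                          calibration = calib)
  attr(series, "detector") <- det
  series
}

# -- scoring -----------------------------------------------------------------

#' Score windows with a fitted detector
#'
#' Deterministic given the fitted state. Scores are oriented so that higher
#' means more abnormal in every family; `decision = score > threshold`.
#'
#' @param det A `trained_detector`.
#' @param windows A `window_set` or feature matrix of matching dimension.
#' @return A `score_series` data.frame: `start_day`, `end_day`, `score`,
#'   `decision`, `calibration`.
#' @export
score <- function(det, windows) {
  stopifnot(inherits(det, "trained_detector"))
  X <- .encode_windows(windows, det$encoding %||% "raw")
  if (ncol(X) != det$dim)
    stop(sprintf("window dimension %d does not match the fitted dimension %d",
                 ncol(X), det$dim), call. = FALSE)
  info <- .win_info(windows)
  fam <- det$spec$family
  s <- switch(fam,
    svm = {
      pr <- stats::predict(det$fit$model, X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # orient: positive decision value must favour the abnormal (TRUE) class
      if (startsWith(colnames(dv)[1], "TRUE")) as.numeric(dv) else -as.numeric(dv)
    },
    cnn = nn_softmax(nn_forward(det$fit$net, X))[, 2],
    ocsvm = {
      pr <- stats::predict(det$fit$model, X, decision.values = TRUE)
      -as.numeric(attr(pr, "decision.values"))
    },
    sae = .recon_error(det$fit$net, X),
    km = .wk_dist(X, det$fit$profile, det$fit$weights^det$fit$beta),
    dc = {
      latent <- nn_forward(det$fit$encoder, X)
      rowSums(sweep(latent, 2, det$fit$profile)^2)
    })
  .score_series(info, s, s > det$threshold)
}
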
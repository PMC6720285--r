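# Hierarchical HMM of daily behavior: the day is split into N time intervals,
# each governed by a dedicated 3-state sub-model (hidden states Tired T,
# Hungry H, Energized E) emitting (ADL, LOC, HRL) triple codes. Sub-model
# start times and state-visit durations are Gaussian per day.

.STATES <- c("T", "H", "E")

#' Hidden circadian states of the behavior model
#' @return `c("T", "H", "E")` (Tired, Hungry, Energized).
#' @export
hidden_states <- function() .STATES

# Build a 120-long emission vector from a named sparse spec
# list("AS_BR_VL" = 0.9, ...); names are combined triple labels.
.emission_vector <- function(spec) {
  e <- numeric(120)
  for (nm in names(spec)) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    e[encode_triple(parts[1], parts[2], parts[3]) + 1L] <- spec[[nm]]
  }
  e / sum(e)
}

.submodel <- function(name, start_mean, start_sd, init, trans, emis,
                      dur_mean, dur_sd) {
  trans <- matrix(trans, 3, 3, byrow = TRUE,
                  dimnames = list(.STATES, .STATES))
  emis_m <- do.call(rbind, lapply(.STATES, function(s) .emission_vector(emis[[s]])))
  rownames(emis_m) <- .STATES
  list(name = name,
       start_mean = start_mean, start_sd = start_sd,
       init = stats::setNames(init / sum(init), .STATES),
       trans = trans,
       emis = emis_m,
       dur_mean = stats::setNames(dur_mean, .STATES),
       dur_sd = stats::setNames(dur_sd, .STATES))
}

# Handcrafted daily archetypes. Emission semantics follow the coded
# vocabulary: nights are dominated by sleeping in the bedroom at very low
# heart rate, mornings by breakfast in the kitchen, afternoons by lunch,
# rest and physical exercise, evenings by housekeeping and dinner.
.default_submodels <- function() {
  list(
    .submodel("night", start_mean = 0, start_sd = 1,
      init = c(T = 0.95, H = 0.03, E = 0.02),
      trans = c(0.80, 0.10, 0.10,
                0.70, 0.20, 0.10,
                0.70, 0.10, 0.20),
      emis = list(
        T = list(AS_BR_VL = 0.92, AT_TO_LO = 0.05, AR_BR_VL = 0.03),
        H = list(AT_TO_LO = 0.55, AE_KI_LO = 0.20, AS_BR_VL = 0.25),
        E = list(AT_TO_LO = 0.50, AR_LR_LO = 0.30, AS_BR_VL = 0.20)),
      dur_mean = c(T = 60, H = 10, E = 10),
      dur_sd = c(T = 15, H = 3, E = 3)),
    .submodel("morning", start_mean = 420, start_sd = 20,
      init = c(T = 0.02, H = 0.90, E = 0.08),
      trans = c(0.30, 0.40, 0.30,
                0.10, 0.30, 0.60,
                0.20, 0.20, 0.60),
      emis = list(
        T = list(AR_LR_LO = 0.80, AR_BR_LO = 0.15, AT_TO_LO = 0.05),
        H = list(AE_KI_ME = 0.85, AE_KI_LO = 0.10, AT_TO_LO = 0.05),
        E = list(AH_LR_ME = 0.50, AH_KI_ME = 0.30, AP_LR_HI = 0.15,
                 AT_TO_ME = 0.05)),
      dur_mean = c(T = 40, H = 35, E = 50),
      dur_sd = c(T = 10, H = 8, E = 12)),
    .submodel("afternoon", start_mean = 750, start_sd = 20,
      init = c(T = 0.10, H = 0.85, E = 0.05),
      trans = c(0.45, 0.15, 0.40,
                0.55, 0.15, 0.30,
                0.50, 0.15, 0.35),
      emis = list(
        T = list(AR_LR_LO = 0.85, AR_BR_LO = 0.10, AT_TO_LO = 0.05),
        H = list(AE_KI_ME = 0.85, AE_KI_HI = 0.05, AT_TO_LO = 0.10),
        E = list(AP_LR_HI = 0.70, AP_LR_VH = 0.15, AH_LR_ME = 0.15)),
      dur_mean = c(T = 60, H = 40, E = 45),
      dur_sd = c(T = 15, H = 10, E = 10)),
    .submodel("evening", start_mean = 1110, start_sd = 20,
      init = c(T = 0.05, H = 0.15, E = 0.80),
      trans = c(0.70, 0.10, 0.20,
                0.60, 0.20, 0.20,
                0.20, 0.50, 0.30),
      emis = list(
        T = list(AR_LR_LO = 0.75, AS_BR_VL = 0.20, AT_TO_LO = 0.05),
        H = list(AE_KI_ME = 0.80, AE_LR_ME = 0.10, AT_TO_LO = 0.10),
        E = list(AH_KI_ME = 0.60, AH_LR_ME = 0.30, AT_TO_ME = 0.10)),
      dur_mean = c(T = 60, H = 45, E = 45),
      dur_sd = c(T = 15, H = 10, E = 12))
  )
}

#' Build the default daily behavior model
#'
#' Returns a hierarchical HMM with `n_submodels` time intervals. The default
#' (`n_submodels = 4`) ships handcrafted night / morning / afternoon / evening
#' sub-models whose emissions follow common-sense semantics of an older adult
#' living alone (sleeping in the bedroom at very low heart rate at night,
#' meals in the kitchen, afternoon rest and exercise, evening housekeeping).
#' Other values of `n_submodels` recycle the four archetypes over evenly
#' spaced start times.
#'
#' @param config Optional list of settings: `n_submodels` (default 4),
#'   `uniform_transitions` (logical; replace every transition row by 1/3),
#'   `submodels` (list indexed by sub-model position, each a list of fields to
#'   override: `start_mean`, `start_sd`, `init`, `trans`, `emis`, `dur_mean`,
#'   `dur_sd`).
#' @return A `daily_behavior_model`: list with `states` and `submodels`.
#' @export
make_default_model <- function(config = list()) {
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), c("n_submodels", "uniform_transitions", "submodels"))
  if (length(unknown) > 0)
    stop("unknown model config entries: ", paste(unknown, collapse = ", "), call. = FALSE)
  n <- config$n_submodels %||% 4L
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n_submodels must be a single integer >= 1", call. = FALSE)
  n <- as.integer(n)
  arch <- .default_submodels()
  if (n == 4L) {
    sms <- arch
  } else {
    sms <- lapply(seq_len(n), function(i) {
      sm <- arch[[(i - 1L) %% 4L + 1L]]
      sm$start_mean <- (i - 1) * 1440 / n
      sm$start_sd <- if (i == 1L) 1 else 20
      sm$name <- paste0("interval", i)
      sm
    })
  }
  if (isTRUE(config$uniform_transitions)) {
    for (i in seq_along(sms))
      sms[[i]]$trans[] <- 1 / 3
  }
  if (!is.null(config$submodels)) {
    for (i in seq_along(config$submodels)) {
      ov <- config$submodels[[i]]
      if (is.null(ov)) next
      if (i > length(sms)) stop("override for nonexistent sub-model ", i, call. = FALSE)
      for (f in names(ov)) sms[[i]][[f]] <- ov[[f]]
      # re-establish state naming on overridden structures
      if (is.matrix(sms[[i]]$trans))
        dimnames(sms[[i]]$trans) <- list(.STATES, .STATES)
      if (is.matrix(sms[[i]]$emis)) rownames(sms[[i]]$emis) <- .STATES
      for (f in c("init", "dur_mean", "dur_sd"))
        if (is.numeric(sms[[i]][[f]]) && length(sms[[i]][[f]]) == 3L)
          names(sms[[i]][[f]]) <- .STATES
    }
  }
  model <- structure(list(states = .STATES, submodels = sms),
                     class = "daily_behavior_model")
  viol <- validate_model(model)
  if (length(viol) > 0)
    stop("model configuration is invalid:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.daily_behavior_model <- function(x, ...) {
  cat(sprintf("<daily_behavior_model> %d sub-models (%s), states %s\n",
              length(x$submodels),
              paste(vapply(x$submodels, `[[`, "", "name"), collapse = ", "),
              paste(x$states, collapse = "/")))
  invisible(x)
}

#' Validate a daily behavior model
#'
#' Checks every type invariant: exactly three hidden states, row-stochastic
#' transition matrices and initial distributions, emission rows summing to one
#' over the 120 triples, positive standard deviations, start-time means in
#' `[0, 1440)` and strictly increasing across sub-models. Validation never
#' throws; it returns a character vector of violations (empty when valid).
#'
#' @param model A `daily_behavior_model`.
#' @param tol Tolerance on stochastic-vector sums (1e-9 at construction;
#'   1e-6 after interpolation).
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validate_model <- function(model, tol = 1e-9) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (!identical(sort(model$states), sort(.STATES)) || length(model$states) != 3L)
    add("states: must be exactly {T, H, E}")
  if (length(model$submodels) < 1L) {
    add("submodels: at least one sub-model required")
    return(v)
  }
  starts <- numeric(0)
  for (i in seq_along(model$submodels)) {
    sm <- model$submodels[[i]]
    tag <- sprintf("submodel %d (%s)", i, sm$name %||% "?")
    if (!is.matrix(sm$trans) || !all(dim(sm$trans) == c(3L, 3L))) {
      add(paste0(tag, ": trans must be 3x3"))
    } else {
      if (any(sm$trans < -tol) || any(sm$trans > 1 + tol))
        add(paste0(tag, ": trans entries outside [0, 1]"))
      rs <- rowSums(sm$trans)
      for (q in which(abs(rs - 1) > tol))
        add(sprintf("%s: transition row %s sums to %.6g", tag, .STATES[q], rs[q]))
    }
    if (!is.matrix(sm$emis) || !all(dim(sm$emis) == c(3L, 120L))) {
      add(paste0(tag, ": emis must be 3x120"))
    } else {
      if (any(sm$emis < -tol)) add(paste0(tag, ": negative emission probability"))
      es <- rowSums(sm$emis)
      for (q in which(abs(es - 1) > tol))
        add(sprintf("%s: emission row %s sums to %.6g", tag, .STATES[q], es[q]))
    }
    if (abs(sum(sm$init) - 1) > tol || any(sm$init < -tol))
      add(paste0(tag, ": initial distribution not stochastic"))
    if (!is.numeric(sm$start_mean) || sm$start_mean < 0 || sm$start_mean >= 1440)
      add(paste0(tag, ": start_mean outside [0, 1440)"))
    if (any(sm$start_sd <= 0) || any(sm$dur_sd <= 0))
      add(paste0(tag, ": standard deviations must be > 0"))
    if (any(sm$dur_mean <= 0))
      add(paste0(tag, ": duration means must be > 0"))
    starts <- c(starts, sm$start_mean)
  }
  if (length(starts) > 1L && any(diff(starts) <= 0))
    add("submodels: nominal start times must be strictly increasing within the day")
  v
}

# Short parameter fingerprint for provenance metadata (polynomial rolling
# hash over the serialized numeric parameters; collision-resistance needs
# are only "did the model change").
.model_fingerprint <- function(model) {
  nums <- unlist(lapply(model$submodels, function(sm)
    c(sm$start_mean, sm$start_sd, sm$init, sm$trans, sm$emis,
      sm$dur_mean, sm$dur_sd)))
  bytes <- as.integer(serialize(signif(nums, 12), NULL)[-(1:14)])
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%08x", h)
}

# Deterministic per-day seed stream derived from the dataset seed.
.day_seed <- function(seed, day) {
  as.integer((as.double(seed) %% 2147483647 * 65537 + day * 2654435) %% 2147483629) + 1L
}

#' Sample one day of behavior from the model
#'
#' For each sub-model in turn, a start time is drawn (Gaussian, clipped to the
#' day and kept non-decreasing across sub-models), the hidden chain is run
#' from its initial distribution, each state visit receives a Gaussian
#' duration (truncated to at least one 5-minute slot) and emits a single
#' triple that is tiled across the slots the visit covers. Slots before the
#' first visit or inside a gap take the temporally nearest emitted triple, so
#' the day is always fully covered.
#'
#' Uses the current R random stream; call `set.seed()` first for
#' reproducibility (or use [sample_dataset()], which manages per-day seeds).
#'
#' @param model A valid `daily_behavior_model`.
#' @param keep_visits Attach a `visits` attribute (data.frame of the hidden
#'   state visits: sub-model, state, start minute, duration, emitted code)?
#' @return Integer vector of 288 triple codes.
#' @export
sample_day <- function(model, keep_visits = FALSE) {
  sms <- model$submodels
  n <- length(sms)
  starts <- vapply(sms, function(sm)
    min(max(stats::rnorm(1, sm$start_mean, sm$start_sd), 0), 1439), numeric(1))
  starts <- cummax(starts)
  limits <- c(starts[-1L], 1440)

  seg_start <- numeric(0); seg_end <- numeric(0); seg_code <- integer(0)
  vis_sm <- integer(0); vis_state <- character(0)
  for (i in seq_len(n)) {
    sm <- sms[[i]]
    t <- starts[i]
    if (t >= limits[i]) next
    state <- sample.int(3L, 1L, prob = sm$init)
    repeat {
      dur <- max(5, stats::rnorm(1, sm$dur_mean[state], sm$dur_sd[state]))
      code <- sample.int(120L, 1L, prob = sm$emis[state, ]) - 1L
      seg_start <- c(seg_start, t)
      seg_end <- c(seg_end, min(t + dur, limits[i]))
      seg_code <- c(seg_code, code)
      vis_sm <- c(vis_sm, i); vis_state <- c(vis_state, .STATES[state])
      t <- t + dur
      if (t >= limits[i]) break
      state <- sample.int(3L, 1L, prob = sm$trans[state, ])
    }
  }

  # Rasterize by slot midpoints; fill gaps with the nearest emitted triple.
  mids <- (0:287) * 5 + 2.5
  idx <- findInterval(mids, seg_start)
  idx[idx == 0L] <- 1L
  in_gap <- mids > seg_end[idx] & idx < length(seg_code)
  nearer_next <- in_gap & (mids - seg_end[idx]) > (seg_start[pmin(idx + 1L, length(seg_code))] - mids)
  idx[nearer_next] <- idx[nearer_next] + 1L
  day <- seg_code[idx]
  if (keep_visits)
    attr(day, "visits") <- data.frame(
      submodel = vis_sm, state = vis_state, start_min = seg_start,
      end_min = seg_end, code = seg_code, stringsAsFactors = FALSE)
  day
}

#' Sample a multi-day behavior dataset
#'
#' Draws `n_days` independent days from the model. Each day uses a random
#' stream derived deterministically from `(seed, day index)`, so a dataset is
#' bit-identical under the same `(model, n_days, seed)` and day `d` of a
#' longer run equals day `d` of a shorter one.
#'
#' @param model A valid `daily_behavior_model`.
#' @param n_days Number of days (365 for a one-year dataset).
#' @param seed Integer seed.
#' @param keep_visits Record the per-day hidden state visits in
#'   `attr(ds, "visits")` (a list of data.frames)?
#' @return A `behavior_dataset`.
#' @export
sample_dataset <- function(model, n_days = 365L, seed = 1L, keep_visits = FALSE) {
  stopifnot(n_days >= 1)
  viol <- validate_model(model, tol = 1e-6)
  if (length(viol) > 0)
    stop("invalid model: ", viol[1], call. = FALSE)
  grid <- matrix(0L, nrow = n_days, ncol = 288L)
  visits <- if (keep_visits) vector("list", n_days) else NULL
  for (d in seq_len(n_days)) {
    set.seed(.day_seed(seed, d))
    day <- sample_day(model, keep_visits = keep_visits)
    grid[d, ] <- day
    if (keep_visits) visits[[d]] <- attr(day, "visits")
  }
  ds <- behavior_dataset(grid, meta = list(
    seed = seed, model_fingerprint = .model_fingerprint(model),
    change = "normal"))
  if (keep_visits) attr(ds, "visits") <- visits
  ds
}
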
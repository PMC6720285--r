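# Behavioral change injection: six parameterized change types (St starting
# time, Du duration, Di disappearance, Sw swap, Lo location, Hr heart rate),
# their unordered pairs, and gradual normal->abnormal parameter blending
# over a perturbation schedule.

.CHANGE_TYPES <- c("St", "Du", "Di", "Sw", "Lo", "Hr")

#' The closed set of behavioral change types
#' @return `c("St", "Du", "Di", "Sw", "Lo", "Hr")`.
#' @export
change_types <- function() .CHANGE_TYPES

# Default change parameterizations, mirroring the prose archetypes:
# breakfast two hours later; afternoon rest three times longer; physical
# exercise disappearing; housekeeping and resting swapped in the evening;
# breakfast moved from the kitchen to the bedroom; resting heart rate
# jumping from low to high.
.default_change_params <- function(type) {
  switch(type,
    St = list(submodel = 2L, shift_min = 120),
    Du = list(submodel = 3L, state = "T", scale = 3),
    Di = list(submodel = NULL, activity = "AP"), # NULL: every sub-model
    Sw = list(submodel = 4L, activities = c("AH", "AR")),
    Lo = list(submodel = 2L, activity = "AE", from = "KI", to = "BR"),
    Hr = list(submodel = 3L, activity = "AR", from = "LO", to = "HI"),
    stop("unknown change type: ", type, call. = FALSE))
}

#' Construct a change specification
#'
#' A `change_spec` names one change type or an unordered pair of distinct
#' types, each with target parameters. Defaults follow the package's
#' archetypal changes (see [apply_change()]); pass `params` to override.
#'
#' @param types Character vector of one or two distinct change types.
#' @param params Optional named list (by type) of parameter overrides. Per
#'   type: `St`: `submodel`, `shift_min`; `Du`: `submodel`, `state`, `scale`;
#'   `Di`: `submodel`, `activity`; `Sw`: `submodel`, `activities` (length 2);
#'   `Lo`/`Hr`: `submodel`, `activity`, `from`, `to`.
#' @return An object of class `change_spec`.
#' @export
change_spec <- function(types, params = list()) {
  types <- as.character(types)
  if (!all(types %in% .CHANGE_TYPES))
    stop("unknown change type(s): ",
         paste(setdiff(types, .CHANGE_TYPES), collapse = ", "), call. = FALSE)
  if (length(types) < 1L || length(types) > 2L)
    stop("a change spec holds one change type or an unordered pair", call. = FALSE)
  if (anyDuplicated(types))
    stop("pair members must be distinct (no repetition such as StSt)", call. = FALSE)
  # canonical enumeration order
  types <- .CHANGE_TYPES[.CHANGE_TYPES %in% types]
  full <- stats::setNames(lapply(types, .default_change_params), types)
  for (t in intersect(names(params), types))
    full[[t]] <- utils::modifyList(full[[t]], params[[t]])
  structure(list(types = types, params = full), class = "change_spec")
}

#' @export
print.change_spec <- function(x, ...) {
  cat(sprintf("<change_spec> %s\n", paste(x$types, collapse = "+")))
  invisible(x)
}

#' All 21 change combinations (6 singletons + 15 unordered pairs)
#'
#' @return List of 21 `change_spec` templates with default parameters, in a
#'   stable order: singletons in canonical type order, then pairs in
#'   lexicographic canonical order.
#' @export
list_change_combinations <- function() {
  singles <- lapply(.CHANGE_TYPES, change_spec)
  pairs <- utils::combn(.CHANGE_TYPES, 2L, simplify = FALSE)
  c(singles, lapply(pairs, change_spec))
}

# -- single-type operators ---------------------------------------------------

.codes_for <- function(activity = NULL, loc = NULL, hrl = NULL) {
  code <- 0:119
  keep <- rep(TRUE, 120)
  if (!is.null(activity)) keep <- keep & (.ADL[code %/% 20L + 1L] %in% activity)
  if (!is.null(loc)) keep <- keep & (.LOC[(code %/% 5L) %% 4L + 1L] %in% loc)
  if (!is.null(hrl)) keep <- keep & (.HRL[code %% 5L + 1L] %in% hrl)
  code[keep]
}

.apply_one_change <- function(model, type, p) {
  if (type == "Di" && is.null(p$submodel)) {
    # the activity is no longer performed at all: drop it everywhere
    for (i in seq_along(model$submodels))
      model <- .apply_one_change(model, "Di", list(submodel = i,
                                                   activity = p$activity))
    return(model)
  }
  i <- p$submodel
  if (is.null(i) || i < 1L || i > length(model$submodels))
    stop("change targets nonexistent sub-model ", i, call. = FALSE)
  sm <- model$submodels[[i]]
  if (type == "St") {
    sm$start_mean <- sm$start_mean + p$shift_min
  } else if (type == "Du") {
    sm$dur_mean[p$state] <- sm$dur_mean[p$state] * p$scale
  } else if (type == "Di") {
    drop <- .codes_for(activity = p$activity) + 1L
    for (s in .STATES) {
      row <- sm$emis[s, ]
      row[drop] <- 0
      if (sum(row) <= 0)
        stop(sprintf("Di change removes the only nonzero emission of state %s in sub-model %d",
                     s, i), call. = FALSE)
      sm$emis[s, ] <- row / sum(row)
    }
  } else if (type == "Sw") {
    a <- p$activities
    if (length(a) != 2L || a[1] == a[2])
      stop("Sw requires two distinct activities", call. = FALSE)
    c1 <- .codes_for(activity = a[1]) + 1L
    c2 <- .codes_for(activity = a[2]) + 1L # aligned by (loc, hrl) order
    for (s in .STATES) {
      tmp <- sm$emis[s, c1]
      sm$emis[s, c1] <- sm$emis[s, c2]
      sm$emis[s, c2] <- tmp
    }
  } else if (type == "Lo") {
    src <- .codes_for(activity = p$activity, loc = p$from) + 1L
    dst <- .codes_for(activity = p$activity, loc = p$to) + 1L # aligned by hrl
    for (s in .STATES) {
      sm$emis[s, dst] <- sm$emis[s, dst] + sm$emis[s, src]
      sm$emis[s, src] <- 0
    }
  } else if (type == "Hr") {
    src <- .codes_for(activity = p$activity, hrl = p$from) + 1L
    dst <- .codes_for(activity = p$activity, hrl = p$to) + 1L # aligned by loc
    for (s in .STATES) {
      sm$emis[s, dst] <- sm$emis[s, dst] + sm$emis[s, src]
      sm$emis[s, src] <- 0
    }
  }
  model$submodels[[i]] <- sm
  model
}

#' Derive the fully abnormal parameter set for a change specification
#'
#' Applies each change type of the spec (in canonical enumeration order) to a
#' copy of the model: `St` shifts the target sub-model's start-time mean by
#' `shift_min` minutes; `Du` rescales a state's duration mean; `Di` zeroes
#' the emission mass of the target activity and renormalizes; `Sw` exchanges
#' the emission roles of two activities (their probability entries are
#' swapped per location/heart-rate cell); `Lo` moves an activity's emission
#' mass to a different home location; `Hr` moves it to a different heart-rate
#' level. All stochastic vectors remain normalized.
#'
#' @param model A valid `daily_behavior_model` (the normal parameter set).
#' @param spec A `change_spec`.
#' @return The abnormal `daily_behavior_model`.
#' @export
apply_change <- function(model, spec) {
  stopifnot(inherits(spec, "change_spec"))
  for (t in spec$types)
    model <- .apply_one_change(model, t, spec$params[[t]])
  viol <- validate_model(model, tol = 1e-6)
  if (length(viol) > 0)
    stop("change produced an invalid model: ", viol[1], call. = FALSE)
  model
}

# -- perturbation schedule ---------------------------------------------------

#' Construct a perturbation schedule
#'
#' The mixing coefficient is 0 up to and including `onset_day`, 1 from
#' `stable_day` on, and ramps linearly in between, optionally with small
#' seeded uniform per-day jitter (clamped to `[0, 1]`, zero amplitude at the
#' boundaries, monotone in expectation).
#'
#' @param onset_day Day the gradual change begins (default 90).
#' @param stable_day Day the abnormal behavior becomes stable (default 180).
#' @param jitter Half-width of the uniform per-day jitter (default 0.05; use
#'   0 for the purely linear ramp).
#' @param seed Integer seed of the jitter stream.
#' @return An object of class `perturbation_schedule`.
#' @export
perturbation_schedule <- function(onset_day = 90L, stable_day = 180L,
                                  jitter = 0.05, seed = 0L) {
  stopifnot(onset_day >= 1, stable_day > onset_day, jitter >= 0, jitter < 0.5)
  structure(list(onset_day = as.integer(onset_day),
                 stable_day = as.integer(stable_day),
                 jitter = jitter, seed = as.integer(seed)),
            class = "perturbation_schedule")
}

# Deterministic uniform in [0,1) from a day index; one LCG step so the
# mixing coefficient never consumes R's global random stream.
.hash_unif <- function(seed, day) {
  x <- (as.double(seed) * 747796405 + day * 2891336453) %% 4294967296
  x <- (x * 1103515245 + 12345) %% 2147483648
  x / 2147483648
}

#' Mixing coefficient lambda(day) of a perturbation schedule
#'
#' @param schedule A `perturbation_schedule`.
#' @param day Integer day index (vectorized), 1-based.
#' @return Numeric fractions in `[0, 1]`: 0 at or before the onset day, 1 at
#'   or after the stabilization day, linear (plus optional seeded jitter)
#'   between.
#' @export
mixing_coefficient <- function(schedule, day) {
  stopifnot(inherits(schedule, "perturbation_schedule"))
  base <- (day - schedule$onset_day) / (schedule$stable_day - schedule$onset_day)
  base <- pmin(pmax(base, 0), 1)
  if (schedule$jitter > 0) {
    inner <- base > 0 & base < 1
    if (any(inner)) {
      u <- vapply(day[inner], function(d) .hash_unif(schedule$seed, d), numeric(1))
      base[inner] <- pmin(pmax(base[inner] + (2 * u - 1) * schedule$jitter, 0), 1)
    }
  }
  base
}

#' Convex interpolation of two behavior models
#'
#' Blends every parameter -- transition rows, emission rows, initial
#' distributions, start-time and duration means and standard deviations -- as
#' `(1 - lam) * normal + lam * abnormal`, renormalizing stochastic vectors.
#' `lam = 0` returns the normal parameters, `lam = 1` the abnormal ones.
#'
#' @param normal,abnormal Two `daily_behavior_model`s with the same structure
#'   (same number of sub-models, same state set).
#' @param lam Mixing fraction in `[0, 1]`.
#' @return The interpolated `daily_behavior_model`.
#' @export
interpolate_models <- function(normal, abnormal, lam) {
  stopifnot(lam >= 0, lam <= 1)
  if (length(normal$submodels) != length(abnormal$submodels) ||
      !identical(normal$states, abnormal$states))
    stop("models are structurally incompatible (sub-model count or state set differ)",
         call. = FALSE)
  if (lam == 0) return(normal)
  if (lam == 1) return(abnormal)
  out <- normal
  for (i in seq_along(normal$submodels)) {
    a <- normal$submodels[[i]]; b <- abnormal$submodels[[i]]
    sm <- a
    sm$start_mean <- (1 - lam) * a$start_mean + lam * b$start_mean
    sm$start_sd <- (1 - lam) * a$start_sd + lam * b$start_sd
    sm$dur_mean <- (1 - lam) * a$dur_mean + lam * b$dur_mean
    sm$dur_sd <- (1 - lam) * a$dur_sd + lam * b$dur_sd
    sm$init <- (1 - lam) * a$init + lam * b$init
    sm$init <- sm$init / sum(sm$init)
    sm$trans <- (1 - lam) * a$trans + lam * b$trans
    sm$trans <- sm$trans / rowSums(sm$trans)
    sm$emis <- (1 - lam) * a$emis + lam * b$emis
    sm$emis <- sm$emis / rowSums(sm$emis)
    out$submodels[[i]] <- sm
  }
  out
}

#' Generate an abnormal behavior dataset with a gradual change
#'
#' For each day `d`, the day is sampled from
#' `interpolate_models(model, apply_change(model, spec), lambda(d))` under the
#' same deterministic per-day seed stream as [sample_dataset()], so days in
#' the normal region (`lambda = 0`) are bit-identical to the corresponding
#' normal dataset under the same seed. The metadata records the change types,
#' schedule boundaries and seed.
#'
#' @param model The normal `daily_behavior_model`.
#' @param spec A `change_spec`.
#' @param schedule A `perturbation_schedule` (default: onset day 90, stable
#'   day 180, jitter seeded from `seed`).
#' @param n_days Number of days (default 365).
#' @param seed Integer seed.
#' @return A `behavior_dataset` whose metadata carries the region boundaries.
#' @export
generate_abnormal_dataset <- function(model, spec, schedule = NULL,
                                      n_days = 365L, seed = 1L) {
  stopifnot(inherits(spec, "change_spec"))
  if (is.null(schedule)) schedule <- perturbation_schedule(seed = seed)
  abnormal <- apply_change(model, spec)
  grid <- matrix(0L, nrow = n_days, ncol = 288L)
  for (d in seq_len(n_days)) {
    lam <- mixing_coefficient(schedule, d)
    m <- interpolate_models(model, abnormal, lam)
    set.seed(.day_seed(seed, d))
    grid[d, ] <- sample_day(m)
  }
  behavior_dataset(grid, meta = list(
    seed = seed,
    model_fingerprint = .model_fingerprint(model),
    change = paste(spec$types, collapse = "+"),
    change_params = spec$params,
    onset_day = schedule$onset_day,
    stable_day = schedule$stable_day,
    jitter = schedule$jitter))
}
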
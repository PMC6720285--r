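test_that("the change catalogue enumerates 6 singletons and 15 pairs", {
  combos <- list_change_combinations()
  expect_length(combos, 21)
  keys <- vapply(combos, function(s) paste(s$types, collapse = ""), "")
  expect_equal(anyDuplicated(keys), 0L)
  expect_false(any(grepl("(St){2}|(Du){2}|(Di){2}|(Sw){2}|(Lo){2}|(Hr){2}", keys)))

  # brute-force enumeration: singletons plus all 2-subsets of the 6 types
  types <- c("St", "Du", "Di", "Sw", "Lo", "Hr")
  expected <- c(types,
                apply(utils::combn(types, 2), 2, paste, collapse = ""))
  expect_setequal(keys, expected)

  expect_error(change_spec(c("St", "St")), "distinct")
  expect_error(change_spec("Xx"), "unknown change type")
  expect_error(change_spec(c("St", "Du", "Di")), "one change type or an unordered pair")
})

test_that("single change operators transform the targeted parameters exactly", {
  m <- make_default_model()

  # St: breakfast two hours later
  ab <- apply_change(m, change_spec("St"))
  expect_equal(ab$submodels[[2]]$start_mean, m$submodels[[2]]$start_mean + 120)

  # identity magnitudes leave the model untouched
  id <- apply_change(m, change_spec(c("St", "Du"),
                                    params = list(St = list(shift_min = 0),
                                                  Du = list(scale = 1))))
  expect_equal(id, m)

  # Du: afternoon resting three times longer
  ab <- apply_change(m, change_spec("Du"))
  expect_equal(ab$submodels[[3]]$dur_mean[["T"]],
               3 * m$submodels[[3]]$dur_mean[["T"]])

  # Di: the activity's emission mass vanishes everywhere, rows renormalized
  ab <- apply_change(m, change_spec("Di"))
  ap_codes <- encode_triple("AP", rep(loc_levels(), each = 5), hrl_levels()) + 1L
  for (sm in ab$submodels) {
    expect_true(all(sm$emis[, ap_codes] == 0))
    expect_equal(rowSums(sm$emis), c(T = 1, H = 1, E = 1))
  }

  # Hr: the mass on (AR, ., LO) moves to (AR, ., HI)
  ab <- apply_change(m, change_spec("Hr"))
  lo <- encode_triple("AR", loc_levels(), "LO") + 1L
  hi <- encode_triple("AR", loc_levels(), "HI") + 1L
  norm3 <- m$submodels[[3]]; ab3 <- ab$submodels[[3]]
  expect_true(all(ab3$emis[, lo] == 0))
  expect_equal(ab3$emis[, hi], norm3$emis[, hi] + norm3$emis[, lo])

  # Lo: breakfast mass moves from the kitchen to the bedroom
  ab <- apply_change(m, change_spec("Lo"))
  ki <- encode_triple("AE", "KI", hrl_levels()) + 1L
  br <- encode_triple("AE", "BR", hrl_levels()) + 1L
  expect_true(all(ab$submodels[[2]]$emis[, ki] == 0))
  expect_equal(ab$submodels[[2]]$emis[, br],
               m$submodels[[2]]$emis[, br] + m$submodels[[2]]$emis[, ki])

  # Sw: the two activities exchange emission roles per (loc, hrl) cell
  ab <- apply_change(m, change_spec("Sw"))
  ah <- encode_triple("AH", rep(loc_levels(), each = 5), hrl_levels()) + 1L
  ar <- encode_triple("AR", rep(loc_levels(), each = 5), hrl_levels()) + 1L
  expect_equal(ab$submodels[[4]]$emis[, ah], m$submodels[[4]]$emis[, ar])
  expect_equal(ab$submodels[[4]]$emis[, ar], m$submodels[[4]]$emis[, ah])
})

test_that("degenerate change specifications are rejected", {
  m <- make_default_model()
  expect_error(apply_change(m, change_spec("Sw",
    params = list(Sw = list(activities = c("AH", "AH"))))), "distinct")
  # removing the only activity a state can emit
  dm <- degenerate_model("AS_BR_VL")
  expect_error(apply_change(dm, change_spec("Di",
    params = list(Di = list(activity = "AS")))), "only nonzero emission")
  expect_error(apply_change(m, change_spec("St",
    params = list(St = list(submodel = 9)))), "nonexistent sub-model")
})

test_that("pair changes on disjoint targets compose order-independently", {
  m <- make_default_model()
  pair <- apply_change(m, change_spec(c("St", "Lo")))
  st_then_lo <- apply_change(apply_change(m, change_spec("St")), change_spec("Lo"))
  lo_then_st <- apply_change(apply_change(m, change_spec("Lo")), change_spec("St"))
  expect_equal(pair, st_then_lo)
  expect_equal(pair, lo_then_st)
})

test_that("the mixing coefficient follows the documented ramp", {
  sch <- perturbation_schedule(jitter = 0)
  expect_equal(mixing_coefficient(sch, 1), 0)
  expect_equal(mixing_coefficient(sch, 89), 0)
  expect_equal(mixing_coefficient(sch, 90), 0)
  expect_equal(mixing_coefficient(sch, 135), 0.5)
  expect_equal(mixing_coefficient(sch, 180), 1)
  expect_equal(mixing_coefficient(sch, 365), 1)

  schj <- perturbation_schedule(jitter = 0.05, seed = 2)
  lam <- mixing_coefficient(schj, 90:180)
  expect_true(all(lam >= 0 & lam <= 1))
  expect_equal(lam[1], 0)
  expect_equal(lam[91], 1)
  # jitter stays within its half-width of the linear ramp
  base <- (90:180 - 90) / 90
  expect_true(all(abs(lam - base) <= 0.05 + 1e-12))
  # deterministic
  expect_identical(lam, mixing_coefficient(schj, 90:180))
})

test_that("model interpolation is convex and preserves stochasticity", {
  m <- make_default_model()
  ab <- apply_change(m, change_spec(c("Sw", "Hr")))
  expect_equal(interpolate_models(m, ab, 0), m)
  expect_equal(interpolate_models(m, ab, 1), ab)
  mid <- interpolate_models(m, ab, 0.5)
  expect_equal(mid$submodels[[3]]$emis,
               (m$submodels[[3]]$emis + ab$submodels[[3]]$emis) / 2)
  for (lam in c(0, 0.25, 0.5, 0.75, 1))
    expect_length(validate_model(interpolate_models(m, ab, lam), tol = 1e-6), 0)

  m1 <- make_default_model(list(n_submodels = 2))
  expect_error(interpolate_models(m, m1, 0.5), "structurally incompatible")
})

test_that("abnormal datasets are normal before onset and changed after stabilization", {
  m <- make_default_model()
  ds <- generate_abnormal_dataset(m, change_spec("Di"), n_days = 250, seed = 21)
  expect_equal(dim(ds$grid), c(250L, 288L))
  expect_equal(ds$meta$change, "Di")
  expect_equal(ds$meta$onset_day, 90)

  # the lambda = 0 region is bit-identical to the normal stream
  norm <- sample_dataset(m, 89, seed = 21)
  expect_identical(ds$grid[1:89, ], norm$grid)

  # the removed activity no longer occurs once the change is stable
  adl <- to_channel_grids(ds)$adl
  expect_equal(sum(adl[200:250, ] == match("AP", adl_levels()) - 1L), 0)
  expect_gt(sum(adl[1:89, ] == match("AP", adl_levels()) - 1L), 0)

  expect_identical(generate_abnormal_dataset(m, change_spec("Di"),
                                             n_days = 250, seed = 21)$grid,
                   ds$grid)
})

test_that("a positive start-time shift delays the activity monotonically in lambda", {
  m <- make_default_model()
  ab <- apply_change(m, change_spec("St")) # breakfast +120 min
  onset_slot <- function(model, n = 100, seed = 33) {
    ds <- sample_dataset(model, n, seed = seed)
    adl <- to_channel_grids(ds)$adl
    # first morning slot (after 05:00) eating in the kitchen
    mean(apply(adl, 1, function(r) {
      i <- which(r == 0L)          # AE
      i <- i[i > 60]
      if (length(i)) min(i) else NA_real_
    }), na.rm = TRUE)
  }
  o <- vapply(c(0, 0.5, 1),
              function(l) onset_slot(interpolate_models(m, ab, l)), numeric(1))
  expect_true(all(diff(o) > 0))
  # at lambda = 1 breakfast is about two hours (24 slots) later
  expect_gt(o[3] - o[1], 15)
})
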
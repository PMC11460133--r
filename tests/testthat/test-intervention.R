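test_that("preset eligibility rules match their design", {
  pop <- make_test_pop(40)
  presets <- intervention_presets(effects = "none")
  # PL: only 13-14-year-olds, regardless of PE
  pop$age <- 15; pop$takes_pe <- TRUE
  expect_false(any(is_eligible(pop, presets$PL)))
  pop$age <- 13
  expect_true(all(is_eligible(pop, presets$PL)))
  # TAPE: PE students only
  pop$age <- 15
  pop$takes_pe <- c(TRUE, FALSE)[rep(1:2, 20)]
  expect_equal(is_eligible(pop, presets$TAPE), pop$takes_pe)
  # NE and PAL: every school attendee
  expect_true(all(is_eligible(pop, presets$NE)))
  expect_true(all(is_eligible(pop, presets$PAL)))
  # nobody outside school is ever eligible
  pop$attends_school <- FALSE
  for (p in presets) expect_false(any(is_eligible(pop, p)))
})

test_that("an all-none effect spec is the identity", {
  pop <- make_test_pop(30)
  spec <- intervention_spec("null", effect_spec())
  expect_identical(apply_intervention(pop, spec)[determinant_names()],
                   pop[determinant_names()])
})

test_that("absolute effects add exactly and aggregate by eligible share", {
  pop <- make_test_pop(100)
  spec <- intervention_spec("up", effect_spec(
    pa_hours_week = list(mode = "absolute", value = 0.2)))
  out <- apply_intervention(pop, spec)
  expect_equal(out$pa_hours_week, pop$pa_hours_week + 0.2)
  # partial eligibility: weighted-mean delta = value * eligible weight share
  spec2 <- intervention_spec("pe", effect_spec(
    pa_hours_week = list(mode = "absolute", value = 0.2)), pe_only = TRUE)
  s <- run_scenario(pop, pop$base_weight, spec2)
  expect_equal(s$table$delta[s$table$determinant == "pa_hours_week"],
               0.2 * s$eligible_weight_share, tolerance = 1e-9)
})

test_that("relative effects scale and ineligible rows stay bit-identical", {
  pop <- make_test_pop(60)
  presets <- intervention_presets(effects = "none")
  pl <- presets$PL
  pl$effects <- effect_spec(social_support = list(mode = "relative",
                                                  value = 0.1))
  out <- apply_intervention(pop, pl)
  young <- pop$age %in% 13:14
  expect_identical(out$social_support[!young], pop$social_support[!young])
  expect_equal(out$social_support[young], pop$social_support[young] * 1.1)
  for (d in setdiff(determinant_names(), "social_support"))
    expect_identical(out[[d]], pop[[d]])
})

test_that("eligibility invariance holds under randomized specs", {
  pop <- make_test_pop(120, seed = 44)
  set.seed(45)
  for (i in 1:20) {
    ages <- sort(sample(12:17, 2, replace = TRUE))
    spec <- intervention_spec(
      paste0("rnd", i),
      effect_spec(
        pa_hours_week = list(mode = sample(c("absolute", "relative"), 1),
                             value = runif(1, -0.5, 2)),
        n_types = list(mode = "absolute", value = sample(-1:3, 1)),
        physical_literacy = list(mode = "relative", value = runif(1, -0.2, 0.2)),
        clamp = sample(c(TRUE, FALSE), 1)),
      pe_only = sample(c(TRUE, FALSE), 1), age_range = ages)
    out <- apply_intervention(pop, spec)
    inel <- !is_eligible(pop, spec)
    for (d in determinant_names())
      expect_identical(out[[d]][inel], pop[[d]][inel])
  }
})

test_that("clamping projects onto valid ranges and rounds counts", {
  pop <- make_test_pop(50)
  cfg <- population_config(n_surveyed = 50, n_clusters = 10, n_districts = 5)
  attr(pop, "config") <- cfg
  spec <- intervention_spec("big", effect_spec(
    pa_hours_week = list(mode = "absolute", value = -100),
    n_settings = list(mode = "relative", value = 0.5),
    physical_literacy = list(mode = "absolute", value = 10),
    clamp = TRUE))
  out <- apply_intervention(pop, spec)
  expect_true(all(out$pa_hours_week == 0))
  expect_true(all(out$n_settings == round(out$n_settings)))
  expect_true(all(out$n_settings <= cfg$dispersion$settings_size))
  expect_true(all(out$physical_literacy <= 20))
  # half-away-from-zero rounding on counts
  pop2 <- pop; pop2$n_settings <- rep(1L, 50)
  spec2 <- intervention_spec("half", effect_spec(
    n_settings = list(mode = "relative", value = 0.5), clamp = TRUE))
  expect_true(all(apply_intervention(pop2, spec2)$n_settings == 2))
  # without clamp, raw arithmetic is returned
  spec3 <- intervention_spec("raw", effect_spec(
    n_settings = list(mode = "relative", value = 0.5), clamp = FALSE))
  expect_equal(apply_intervention(pop2, spec3)$n_settings, rep(1.5, 50))
})

test_that("strata overrides supersede the base effect value", {
  pop <- make_test_pop(80)
  spec <- intervention_spec("strat", effect_spec(
    pa_hours_week = list(mode = "absolute", value = 1,
                         overrides = list(list(gender = "female", value = 3),
                                          list(age_range = c(12, 12),
                                               value = 0)))))
  out <- apply_intervention(pop, spec)
  added <- out$pa_hours_week - pop$pa_hours_week
  expect_true(all(added[pop$age == 12] == 0))
  expect_true(all(abs(added[pop$gender == "female" & pop$age != 12] - 3)
                  < 1e-12))
  expect_true(all(abs(added[pop$gender != "female" & pop$age != 12] - 1)
                  < 1e-12))
})

test_that("unknown determinant keys are rejected", {
  expect_error(effect_spec(not_a_determinant = list(mode = "absolute",
                                                    value = 1)),
               "unknown determinant")
  expect_error(effect_spec(pa_hours_week = list(mode = "relative",
                                                value = -1.5)), "-1")
})

test_that("percent change inverts its definition", {
  expect_equal(percent_change(10, 10.5), 5.0)
  expect_equal(percent_change(3, 3), 0)
  expect_equal(percent_change(16.49, 16.49 * 1.036), 3.6, tolerance = 1e-9)
  expect_error(percent_change(0, 1), "zero baseline")
})

test_that("null scenarios produce zero deltas and percent changes", {
  pop <- make_test_pop(70)
  s <- run_scenario(pop, pop$base_weight,
                    intervention_spec("null", effect_spec()))
  expect_true(all(s$table$delta == 0))
  expect_true(all(s$table$percent_change == 0))
  expect_equal(s$eligible_weight_share, 1)
})

test_that("scorecard ranks deltas with lexicographic tie-breaking", {
  d1 <- rbind(pa = c(TAPE = 0.08, PL = -0.06, PAL = 0.05, NE = 0.2))
  expect_equal(unclass(rank_interventions(d1))[1, ],
               c(TAPE = 2L, PL = 4L, PAL = 3L, NE = 1L))
  d2 <- rbind(types = c(TAPE = 0.34, PL = 1.05, PAL = 0.15, NE = 1.57))
  expect_equal(unclass(rank_interventions(d2))[1, ],
               c(TAPE = 3L, PL = 2L, PAL = 4L, NE = 1L))
  dt <- rbind(x = c(B = 1, A = 1, C = 1))
  expect_equal(unclass(rank_interventions(dt))[1, ],
               c(B = 2L, A = 1L, C = 3L))
  # each row is a permutation and ranks decrease with delta
  set.seed(50)
  dm <- matrix(rnorm(20), 5, dimnames = list(NULL, c("a", "b", "c", "d")))
  sc <- rank_interventions(dm)
  for (i in 1:5) {
    expect_setequal(sc[i, ], 1:4)
    expect_true(all(diff(dm[i, order(sc[i, ])]) <= 0))
  }
})

test_that("calibrated effects recover the published aggregate deltas", {
  pop <- default_filtered_pop(seed = 3, n = 3000)
  pop$weight <- pop$base_weight
  ef <- calibrate_effects("PL", pop, age_range = c(13L, 14L))
  spec <- intervention_spec("PL", ef, age_range = c(13L, 14L))
  s <- run_scenario(pop, pop$weight, spec)
  tg <- reported_effect_targets()
  for (d in determinant_names()) {
    row <- tg[tg$intervention == "PL" & tg$determinant == d, ]
    got <- s$table[s$table$determinant == d, ]
    if (row$unit == "absolute")
      expect_equal(got$delta, row$value, tolerance = 1e-9)
    else expect_equal(got$percent_change, row$value, tolerance = 1e-9)
  }
})
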
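# Shipped intervention presets: eligibility rules, cost components and the
# published national-level effect targets, back-solved into per-eligible
# absolute effects at run time.

#' Published national-level effect targets
#'
#' The population-level changes reported for the four modelled interventions:
#' absolute deltas for weekly PA hours, settings and types, and percent
#' changes (of the baseline mean) for the physical literacy and social
#' support scores.
#'
#' @return A data frame with columns `determinant`, `intervention`, `value`,
#'   `unit` (`"absolute"` or `"percent"`).
#' @export
reported_effect_targets <- function() {
  iv <- c("TAPE", "PL", "PAL", "NE")
  rbind(
    data.frame(determinant = "pa_hours_week", intervention = iv,
               value = c(0.08, -0.06, 0.05, 0.20), unit = "absolute"),
    data.frame(determinant = "n_settings", intervention = iv,
               value = c(1.29, 0.73, 1.21, 1.75), unit = "absolute"),
    data.frame(determinant = "n_types", intervention = iv,
               value = c(0.34, 1.05, 0.15, 1.57), unit = "absolute"),
    data.frame(determinant = "physical_literacy", intervention = iv,
               value = c(0.43, 3.6, 3.3, 0.12), unit = "percent"),
    data.frame(determinant = "social_support", intervention = iv,
               value = c(1.46, 1.9, 5, 0.57), unit = "percent")
  )
}

# Eligibility and cost skeletons for the four shipped interventions.
# TAPE: technologically augmented PE (PE students only); PL: peer-led
# mentoring (ages 13-14 only); PAL: physically active learning (all);
# NE: natural environment play area (all).
preset_skeletons <- function() {
  list(
    TAPE = list(pe_only = TRUE, age_range = c(12L, 17L),
                cost_inputs = data.frame(
                  label = "teacher training, resources and mentor support",
                  amount = 8064.82, currency = "AUD", year = 2020L),
                printed_per_school = 7588.54, printed_per_student = 10.25),
    PL = list(pe_only = FALSE, age_range = c(13L, 14L),
              cost_inputs = data.frame(
                label = "facilitator training, materials and implementation",
                amount = 2520, currency = "GBP", year = 2019L),
              printed_per_school = 5315.64, printed_per_student = 7.18),
    PAL = list(pe_only = FALSE, age_range = c(12L, 17L),
               cost_inputs = data.frame(
                 label = c("teacher training", "school resources"),
                 amount = c(910, 180), currency = c("GBP", "USD"),
                 year = c(2019L, 2011L)),
               printed_per_school = 2208.53, printed_per_student = 2.98),
    NE = list(pe_only = FALSE, age_range = c(12L, 17L),
              cost_inputs = data.frame(
                label = "schoolyard greening design and implementation",
                amount = 50000, currency = "EUR", year = 2021L),
              printed_per_school = 88755, printed_per_student = 119.40)
  )
}

#' Back-solve calibrated per-eligible effects for one intervention
#'
#' Inverts a published population-level delta into the constant absolute
#' per-eligible effect that reproduces it exactly: `effect = delta / share`,
#' where `share` is the intervention's eligible weight share and, for the
#' percent-reported scores, `delta = baseline mean * percent / 100`. The
#' returned [effect_spec()] has `clamp = FALSE` so the inversion is exact
#' under the linearity of the weighted mean.
#'
#' @param name Intervention name present in `targets`.
#' @param pop Filtered population data frame.
#' @param weights Calibrated weights (defaults to `pop$weight` then
#'   `pop$base_weight`).
#' @param targets Target table, see [reported_effect_targets()].
#' @param pe_only,age_range Eligibility rule used to compute the share.
#' @return An [effect_spec()] with absolute per-eligible effects.
#' @export
calibrate_effects <- function(name, pop, weights = NULL,
                              targets = reported_effect_targets(),
                              pe_only = FALSE, age_range = c(12L, 17L)) {
  if (is.null(weights))
    weights <- if (!is.null(pop$weight)) pop$weight else pop$base_weight
  dummy <- intervention_spec(name, pe_only = pe_only, age_range = age_range)
  share <- sum(weights[is_eligible(pop, dummy)]) / sum(weights)
  if (share <= 0)
    stop(sprintf("intervention '%s' has no eligible participants", name),
         call. = FALSE)
  tg <- targets[targets$intervention == name, ]
  if (nrow(tg) == 0)
    stop(sprintf("no targets for intervention '%s'", name), call. = FALSE)
  entries <- list()
  for (i in seq_len(nrow(tg))) {
    d <- tg$determinant[i]
    delta <- if (tg$unit[i] == "percent")
      weighted_mean(pop[[d]], weights) * tg$value[i] / 100
    else tg$value[i]
    entries[[d]] <- list(mode = "absolute", value = delta / share)
  }
  do.call(effect_spec, c(entries, list(clamp = FALSE)))
}

#' Shipped intervention presets
#'
#' The four modelled interventions with their eligibility rules and cost
#' components. With `effects = "calibrated"` (the default when a population
#' is supplied) each preset's effect spec is back-solved from the published
#' national-level deltas via [calibrate_effects()]; `effects =
#' "illustrative"` ships simple round-number effects for tutorials; `effects
#' = "none"` leaves all effects empty.
#'
#' @param pop Filtered population data frame (required for `"calibrated"`).
#' @param weights Calibrated weights.
#' @param effects `"calibrated"`, `"illustrative"` or `"none"`.
#' @return Named list of four [intervention_spec()] objects
#'   (`TAPE`, `PL`, `PAL`, `NE`).
#' @export
intervention_presets <- function(pop = NULL, weights = NULL,
                                 effects = c("calibrated", "illustrative",
                                             "none")) {
  effects <- match.arg(effects)
  sk <- preset_skeletons()
  out <- lapply(names(sk), function(nm) {
    s <- sk[[nm]]
    ef <- switch(effects,
      none = effect_spec(),
      illustrative = effect_spec(
        pa_hours_week = list(mode = "absolute", value = 0.5),
        n_settings = list(mode = "absolute", value = 1),
        n_types = list(mode = "absolute", value = 1),
        physical_literacy = list(mode = "relative", value = 0.05),
        social_support = list(mode = "relative", value = 0.05),
        clamp = TRUE),
      calibrated = {
        if (is.null(pop))
          stop("calibrated presets need a population", call. = FALSE)
        calibrate_effects(nm, pop, weights,
                          pe_only = s$pe_only, age_range = s$age_range)
      })
    intervention_spec(nm, effects = ef, pe_only = s$pe_only,
                      age_range = s$age_range, cost_inputs = s$cost_inputs)
  })
  names(out) <- names(sk)
  out
}
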
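# Intervention eligibility and effect application, scenario estimates,
# percent changes and the cross-intervention scorecard.

#' Per-determinant effect specification
#'
#' Describes how an intervention changes each determinant for eligible
#' participants. For each determinant give a `mode` (`"absolute"`: add
#' `value` in determinant units; `"relative"`: multiply by `1 + value`;
#' `"none"`: leave unchanged) and a `value`. Strata overrides replace the base
#' value for participants in a given age range and/or gender.
#'
#' @param ... Named determinant entries, each a list with elements `mode`,
#'   `value`, and optional `overrides` (a list of lists with elements
#'   `age_range` (length-2 inclusive) and/or `gender`, plus `value`).
#'   Determinants not named default to mode `"none"`.
#' @param clamp If `TRUE`, post-effect values are projected onto the
#'   determinant's valid range: hours floored at 0, counts rounded half away
#'   from zero and kept within `[0, checklist size]`, scores kept within their
#'   score bounds. If `FALSE`, raw arithmetic results are returned.
#' @return A list of class `"effect_spec"`.
#' @export
#' @examples
#' effect_spec(pa_hours_week = list(mode = "absolute", value = 0.2))
effect_spec <- function(..., clamp = FALSE) {
  entries <- list(...)
  if (length(entries) == 1 && is.null(names(entries)) &&
      is.list(entries[[1]]) && !is.null(names(entries[[1]])) &&
      all(names(entries[[1]]) %in% DETERMINANTS))
    entries <- entries[[1]]
  bad <- setdiff(names(entries), DETERMINANTS)
  if (length(bad))
    stop(sprintf("unknown determinant key in effect spec: '%s'", bad[1]),
         call. = FALSE)
  spec <- setNames(vector("list", length(DETERMINANTS)), DETERMINANTS)
  for (d in DETERMINANTS) {
    e <- entries[[d]]
    if (is.null(e)) e <- list(mode = "none", value = 0)
    e$mode <- match.arg(e$mode, c("absolute", "relative", "none"))
    if (e$mode == "relative" && e$value <= -1)
      stop("relative effect values must exceed -1", call. = FALSE)
    spec[[d]] <- e
  }
  structure(list(effects = spec, clamp = isTRUE(clamp)),
            class = "effect_spec")
}

#' Intervention specification
#'
#' Bundles a name, an eligibility rule (`pe_only`, inclusive `age_range`), an
#' [effect_spec()], and optional cost inputs (see [cost_to_nzd()]).
#'
#' @param name Intervention name (e.g. `"TAPE"`, `"PL"`, `"PAL"`, `"NE"`).
#' @param effects An [effect_spec()].
#' @param pe_only If `TRUE`, only participants taking PE are eligible.
#' @param age_range Inclusive integer age interval `c(min, max)`; default
#'   all ages.
#' @param cost_inputs Optional `data.frame(label, amount, currency, year)` of
#'   cost components, with attribute handling via `basis`.
#' @param basis `"per_school"` or `list(type = "total_for_n_schools", n = k)`.
#' @return A list of class `"intervention_spec"`.
#' @export
intervention_spec <- function(name, effects = effect_spec(),
                              pe_only = FALSE, age_range = c(12L, 17L),
                              cost_inputs = NULL, basis = "per_school") {
  stopifnot(length(age_range) == 2, age_range[1] <= age_range[2])
  structure(list(name = name, effects = effects, pe_only = isTRUE(pe_only),
                 age_range = as.integer(age_range),
                 cost_inputs = cost_inputs, basis = basis),
            class = "intervention_spec")
}

#' Intervention eligibility
#'
#' A participant is eligible iff they attend school, take PE when the
#' intervention is PE-only, and their age lies in the intervention's age
#' range.
#'
#' @param pop Population data frame.
#' @param spec An [intervention_spec()].
#' @return Logical vector, one element per participant.
#' @export
is_eligible <- function(pop, spec) {
  pop$attends_school &
    (!spec$pe_only | pop$takes_pe) &
    pop$age >= spec$age_range[1] & pop$age <= spec$age_range[2]
}

# Resolve the effect value per participant, honouring strata overrides
# (later overrides win where several match).
resolve_effect_value <- function(e, pop) {
  v <- rep(e$value, nrow(pop))
  for (ov in e$overrides) {
    sel <- rep(TRUE, nrow(pop))
    if (!is.null(ov$age_range))
      sel <- sel & pop$age >= ov$age_range[1] & pop$age <= ov$age_range[2]
    if (!is.null(ov$gender)) sel <- sel & pop$gender %in% ov$gender
    v[sel] <- ov$value
  }
  v
}

#' Apply an intervention to the population's determinants
#'
#' For eligible participants each determinant is updated per the effect spec
#' (absolute: `y + v`; relative: `y * (1 + v)`); strata overrides supersede
#' the base value. With `clamp = TRUE` the results are projected onto the
#' determinant's valid range (counts rounded half away from zero). Ineligible
#' participants' determinant values are returned unchanged; the input is not
#' mutated.
#'
#' @param pop Population data frame with determinant columns.
#' @param spec An [intervention_spec()].
#' @return A copy of `pop` with updated determinant columns.
#' @export
apply_intervention <- function(pop, spec) {
  elig <- is_eligible(pop, spec)
  out <- pop
  cfg <- attr(pop, "config")
  for (d in DETERMINANTS) {
    e <- spec$effects$effects[[d]]
    if (e$mode == "none") next
    v <- resolve_effect_value(e, pop)[elig]
    y <- out[[d]][elig]
    y2 <- if (e$mode == "absolute") y + v else y * (1 + v)
    if (spec$effects$clamp) {
      if (d %in% c("n_settings", "n_types")) {
        y2 <- round_half_away(y2)
        cap <- if (!is.null(cfg)) {
          if (d == "n_settings") cfg$dispersion$settings_size
          else cfg$dispersion$types_size
        } else Inf
        y2 <- pmin(pmax(y2, 0), cap)
      } else if (d == "pa_hours_week") {
        y2 <- pmax(y2, 0)
      } else {
        b <- if (!is.null(cfg)) cfg$score_bounds[[d]] else c(-Inf, Inf)
        y2 <- pmin(pmax(y2, b[1]), b[2])
      }
    }
    out[[d]][elig] <- y2
  }
  attr(out, "config") <- cfg
  out
}

#' Percent change of a mean
#'
#' `100 * (post - baseline) / baseline`.
#'
#' @param baseline_mean Baseline mean (non-zero).
#' @param post_mean Post-intervention mean.
#' @return Percent change.
#' @export
percent_change <- function(baseline_mean, post_mean) {
  if (any(baseline_mean == 0))
    stop("percent change undefined for zero baseline", call. = FALSE)
  100 * (post_mean - baseline_mean) / baseline_mean
}

#' Run one intervention scenario
#'
#' Computes baseline and post-intervention survey estimates for every
#' determinant, the scenario deltas (`post mean - baseline mean`), percent
#' changes, and the eligible weight share.
#'
#' @param pop Filtered population data frame.
#' @param weights Calibrated weights (defaults to `pop$weight`, then
#'   `pop$base_weight`).
#' @param spec An [intervention_spec()].
#' @param level Confidence level.
#' @return An object of class `"scenario_result"`: list with `name`, `table`
#'   (a data frame with baseline/post means, SEs, CIs, `delta`,
#'   `percent_change` per determinant) and `eligible_weight_share`.
#' @export
run_scenario <- function(pop, weights = NULL, spec, level = 0.95) {
  if (is.null(weights))
    weights <- if (!is.null(pop$weight)) pop$weight else pop$base_weight
  base <- summarize_determinants(pop, weights, "weighted", level)
  post_pop <- apply_intervention(pop, spec)
  post <- summarize_determinants(post_pop, weights, "weighted", level)
  share <- sum(weights[is_eligible(pop, spec)]) / sum(weights)
  tab <- data.frame(
    determinant = base$determinant,
    baseline_mean = base$mean, baseline_se = base$se,
    baseline_ci_low = base$ci_low, baseline_ci_high = base$ci_high,
    post_mean = post$mean, post_se = post$se,
    post_ci_low = post$ci_low, post_ci_high = post$ci_high,
    delta = post$mean - base$mean,
    percent_change = 100 * (post$mean - base$mean) / base$mean,
    stringsAsFactors = FALSE
  )
  structure(list(name = spec$name, table = tab,
                 eligible_weight_share = share, level = level),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, digits = 3, ...) {
  cat(sprintf("Scenario '%s' (eligible weight share %.1f%%)\n",
              x$name, 100 * x$eligible_weight_share))
  print(data.frame(determinant = x$table$determinant,
                   baseline = round(x$table$baseline_mean, digits),
                   post = round(x$table$post_mean, digits),
                   delta = round(x$table$delta, digits),
                   pct = round(x$table$percent_change, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Rank interventions per determinant
#'
#' Rank 1 is the largest improvement (delta) on each determinant, descending;
#' ties are broken by intervention name in lexicographic order.
#'
#' @param deltas Numeric matrix of deltas, rows = determinants, columns =
#'   interventions (column names required; at least two columns).
#' @return An integer matrix of class `"scorecard"` of the same shape; each
#'   row is a permutation of `1..k`.
#' @export
#' @examples
#' d <- rbind(pa_hours_week = c(TAPE = 0.08, PL = -0.06, PAL = 0.05, NE = 0.2))
#' rank_interventions(d)
rank_interventions <- function(deltas) {
  deltas <- as.matrix(deltas)
  if (ncol(deltas) < 2) stop("need at least two interventions", call. = FALSE)
  if (is.null(colnames(deltas)))
    stop("deltas must have intervention column names", call. = FALSE)
  if (any(!is.finite(deltas))) stop("deltas must be finite", call. = FALSE)
  ord <- order(colnames(deltas))
  ranks <- t(apply(deltas[, ord, drop = FALSE], 1, function(d)
    rank(-d, ties.method = "first")))
  out <- matrix(NA_integer_, nrow(deltas), ncol(deltas),
                dimnames = dimnames(deltas))
  out[, ord] <- ranks
  class(out) <- c("scorecard", class(out))
  out
}

#' @export
print.scorecard <- function(x, ...) {
  cat("Intervention scorecard (1 = most improvement):\n")
  print(unclass(x))
  invisible(x)
}
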
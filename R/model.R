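#' Fit the full intervention scenario model
#'
#' Runs the whole pipeline in memory: generate the synthetic survey
#' population, restrict to school attendees, build margin tables and rake the
#' weights, estimate baseline determinant means with cluster-robust CIs, run
#' every intervention scenario, rank the interventions on a scorecard, and
#' cost national rollout.
#'
#' @param config A [population_config()] (its `seed` drives all randomness).
#' @param interventions Named list of [intervention_spec()]s, or one of the
#'   preset selectors `"calibrated"` / `"illustrative"` (see
#'   [intervention_presets()]); `"calibrated"` (default) back-solves the
#'   published national-level deltas into per-eligible effects on the
#'   generated population.
#' @param margin_vars Margin definitions for raking (see
#'   [generate_margins()]).
#' @param margin_scale Scale factor from sample counts to population totals.
#' @param level Confidence level for all intervals.
#' @param n_schools,students_per_school Costing denominators.
#' @param tol,max_iter Raking controls.
#' @return An object of class `"scenario_model"` with elements `population`
#'   (filtered, with calibrated `weight`), `raking`, `baseline` (weighted
#'   summary), `baseline_unweighted`, `scenarios` (list of
#'   [run_scenario()] results), `scorecard`, `costs` (data frame), `config`
#'   and `call`. Methods: `print`, `summary`, `coef` (delta matrix,
#'   determinants x interventions), `plot` (estimate panels with CI
#'   whiskers).
#' @export
#' @examples
#' m <- scenario_model(population_config(n_surveyed = 800, seed = 7))
#' coef(m)
scenario_model <- function(config = population_config(),
                           interventions = "calibrated",
                           margin_vars = list(c("district", "gender"),
                                              "primary_ethnicity"),
                           margin_scale = 55,
                           level = 0.95,
                           n_schools = 376, students_per_school = 740,
                           tol = 1e-8, max_iter = 200) {
  cl <- match.call()
  pop_all <- generate_population(config)
  pop <- apply_school_filter(pop_all)
  margins <- generate_margins(pop, margin_vars, scale = margin_scale)
  pop <- rake_population(pop, margins, margin_vars,
                         tol = tol, max_iter = max_iter)

  if (is.character(interventions))
    interventions <- intervention_presets(pop, pop$weight,
                                          effects = interventions)
  if (anyDuplicated(vapply(interventions, `[[`, "", "name")))
    stop("intervention names must be unique", call. = FALSE)

  baseline <- summarize_determinants(pop, scheme = "weighted", level = level)
  baseline_unw <- summarize_determinants(pop, scheme = "unweighted")

  scenarios <- lapply(interventions, function(sp)
    run_scenario(pop, pop$weight, sp, level = level))
  names(scenarios) <- vapply(interventions, `[[`, "", "name")

  scorecard <- NULL
  if (length(scenarios) >= 2) {
    deltas <- vapply(scenarios, function(s)
      setNames(s$table$delta, s$table$determinant),
      numeric(length(DETERMINANTS)))
    scorecard <- rank_interventions(deltas)
  }

  costs <- do.call(rbind, lapply(interventions, function(sp) {
    if (is.null(sp$cost_inputs)) return(NULL)
    cr <- cost_intervention(sp, n_schools = n_schools,
                            students_per_school = students_per_school)
    data.frame(intervention = sp$name,
               per_school_nzd = cr$per_school_nzd,
               per_student_nzd = cr$per_student_nzd,
               national_nzd = cr$national_nzd,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(costs)) rownames(costs) <- NULL

  structure(list(population = pop, margins = margins,
                 raking = attr(pop, "raking"),
                 baseline = baseline, baseline_unweighted = baseline_unw,
                 scenarios = scenarios, scorecard = scorecard,
                 costs = costs, config = config, level = level, call = cl),
            class = "scenario_model")
}

#' @export
print.scenario_model <- function(x, ...) {
  cat("School-based PA intervention scenario model\n")
  cat(sprintf("  analytic sample: %d school attendees (of %d surveyed), %d clusters\n",
              nrow(x$population), x$config$n_surveyed,
              length(unique(x$population$cluster_id))))
  cat(sprintf("  raking: %s (max margin deviation %.2g)\n",
              if (x$raking$converged) "converged" else "not converged",
              x$raking$max_margin_deviation))
  cat(sprintf("  interventions: %s\n",
              paste(names(x$scenarios), collapse = ", ")))
  cat("Baseline weighted means:\n")
  b <- x$baseline
  for (i in seq_len(nrow(b)))
    cat(sprintf("  %-35s %6.2f (%g%% CI %.2f, %.2f)\n",
                DETERMINANT_LABELS[b$determinant[i]], b$mean[i],
                100 * x$level, b$ci_low[i], b$ci_high[i]))
  invisible(x)
}

#' @export
summary.scenario_model <- function(object, ...) {
  tabs <- lapply(names(object$scenarios), function(nm) {
    t <- object$scenarios[[nm]]$table
    data.frame(intervention = nm, t, stringsAsFactors = FALSE)
  })
  out <- list(baseline = object$baseline,
              scenarios = do.call(rbind, tabs),
              scorecard = object$scorecard,
              costs = object$costs)
  class(out) <- "summary.scenario_model"
  out
}

#' @export
print.summary.scenario_model <- function(x, ...) {
  cat("Baseline (weighted):\n")
  print(x$baseline, row.names = FALSE, digits = 4)
  cat("\nScenario deltas:\n")
  print(x$scenarios[, c("intervention", "determinant", "baseline_mean",
                        "post_mean", "delta", "percent_change")],
        row.names = FALSE, digits = 4)
  if (!is.null(x$scorecard)) {
    cat("\n"); print(x$scorecard)
  }
  if (!is.null(x$costs)) {
    cat("\nNational rollout costs (NZD 2019):\n")
    print(x$costs, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.scenario_model <- function(object, ...) {
  vapply(object$scenarios, function(s)
    setNames(s$table$delta, s$table$determinant),
    numeric(length(DETERMINANTS)))
}

#' Plot determinant estimates across conditions
#'
#' One panel per determinant: the baseline and each intervention condition's
#' point estimate with CI whiskers (whiskers suppressed when the SE is 0).
#'
#' @param x A [scenario_model()].
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.scenario_model <- function(x, ...) {
  conds <- c("baseline", names(x$scenarios))
  old <- par(mfrow = c(2, 3), mar = c(6, 4, 3, 1))
  on.exit(par(old))
  for (d in DETERMINANTS) {
    b <- x$baseline[x$baseline$determinant == d, ]
    means <- c(b$mean, vapply(x$scenarios, function(s)
      s$table$post_mean[s$table$determinant == d], 0))
    lo <- c(b$ci_low, vapply(x$scenarios, function(s)
      s$table$post_ci_low[s$table$determinant == d], 0))
    hi <- c(b$ci_high, vapply(x$scenarios, function(s)
      s$table$post_ci_high[s$table$determinant == d], 0))
    k <- length(means)
    plot.new()
    ylim <- range(lo, hi)
    if (diff(ylim) == 0) ylim <- ylim + c(-1, 1) * max(1e-6, abs(ylim[1]) * 0.01)
    plot.window(xlim = c(0.5, k + 0.5), ylim = ylim)
    box(); axis(2)
    axis(1, at = seq_len(k), labels = conds, las = 2)
    points(seq_len(k), means, pch = 19)
    has_w <- (hi - lo) > 0
    if (any(has_w))
      arrows(seq_len(k)[has_w], lo[has_w], seq_len(k)[has_w], hi[has_w],
             angle = 90, code = 3, length = 0.04)
    title(main = DETERMINANT_LABELS[[d]], cex.main = 0.9)
  }
  invisible(x)
}
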
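# Iterative proportional fitting (raking) of survey weights to known
# population margins.

# Split a margin table data.frame (variable, category, total) into a named
# list of named total vectors, validating positivity.
split_margins <- function(margins) {
  if (!all(c("variable", "category", "total") %in% names(margins)))
    stop("margins must have columns variable, category, total", call. = FALSE)
  if (any(margins$total <= 0))
    stop("all margin totals must be positive", call. = FALSE)
  lapply(split(margins, margins$variable), function(m)
    setNames(m$total, m$category))
}

check_raking_inputs <- function(base_weights, memberships, margins_list) {
  if (any(base_weights <= 0) || any(!is.finite(base_weights)))
    stop("base weights must be positive and finite", call. = FALSE)
  grand <- vapply(margins_list, sum, 0)
  if (max(grand) - min(grand) > 1e-6 * max(grand))
    stop(sprintf(
      "margin-consistency error: grand totals differ across margins (%s)",
      paste(format(grand), collapse = ", ")), call. = FALSE)
  for (v in names(margins_list)) {
    if (!v %in% names(memberships))
      stop(sprintf("no membership column for margin '%s'", v), call. = FALSE)
    mem <- as.character(memberships[[v]])
    missing_cat <- setdiff(unique(mem), names(margins_list[[v]]))
    if (length(missing_cat))
      stop(sprintf("margin '%s' has no total for category '%s'",
                   v, missing_cat[1]), call. = FALSE)
    empty <- setdiff(names(margins_list[[v]]), unique(mem))
    if (length(empty))
      stop(sprintf("infeasible margin: category '%s' of margin '%s' has no participants",
                   empty[1], v), call. = FALSE)
  }
  grand[1]
}

#' Maximum relative margin deviation
#'
#' Largest absolute relative gap between the weighted category totals and the
#' margin totals, over all margins and categories:
#' `max |sum(w in category) - total| / total`.
#'
#' @param weights Positive weights, one per participant.
#' @param memberships Data frame with one column per margin variable giving
#'   each participant's category (column names matching `margins$variable`).
#' @param margins Margin table (`variable`, `category`, `total`), as produced
#'   by [generate_margins()].
#' @return A non-negative scalar.
#' @export
margin_deviation <- function(weights, memberships, margins) {
  ml <- split_margins(margins)
  dev <- 0
  for (v in names(ml)) {
    mem <- as.character(memberships[[v]])
    cur <- vapply(split(weights, factor(mem, levels = names(ml[[v]]))),
                  sum, 0)
    dev <- max(dev, max(abs(cur - ml[[v]]) / ml[[v]]))
  }
  dev
}

#' Calibrate weights by iterative proportional fitting (raking)
#'
#' Cyclically rescales the weights margin-by-margin so that, within each
#' margin, the weighted category totals match the known population totals.
#' One iteration is a full cycle over all margins in the order given by
#' `margins$variable`. Iteration stops when the maximum relative margin
#' deviation falls to `tol` or after `max_iter` cycles.
#'
#' Margins must be consistent: every margin's totals must sum to the same
#' grand total within `1e-6` relative, every participant must have a category
#' in every margin, and every margin category must contain at least one
#' participant.
#'
#' @inheritParams margin_deviation
#' @param base_weights Positive starting weights (design weights).
#' @param tol Convergence tolerance on the maximum relative margin deviation.
#' @param max_iter Maximum number of full cycles.
#' @return An object of class `"raking_result"`: a list with `weights`
#'   (calibrated, positive), `n_iterations`, `converged`, and
#'   `max_margin_deviation`.
#' @export
#' @examples
#' mem <- data.frame(row = c("A", "A", "B", "B"), col = c("X", "Y", "X", "Y"))
#' marg <- data.frame(variable = c("row", "row", "col", "col"),
#'                    category = c("A", "B", "X", "Y"),
#'                    total = c(3, 1, 2, 2))
#' ipf_rake(rep(1, 4), mem, marg)$weights
ipf_rake <- function(base_weights, memberships, margins,
                     tol = 1e-8, max_iter = 200) {
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  ml <- split_margins(margins)
  check_raking_inputs(base_weights, memberships, ml)

  w <- base_weights
  mem_f <- lapply(names(ml), function(v)
    factor(as.character(memberships[[v]]), levels = names(ml[[v]])))
  names(mem_f) <- names(ml)

  it <- 0L
  dev <- margin_deviation(w, memberships, margins)
  while (dev > tol && it < max_iter) {
    for (v in names(ml)) {
      cur <- vapply(split(w, mem_f[[v]]), sum, 0)
      w <- w * (ml[[v]] / cur)[as.integer(mem_f[[v]])]
    }
    it <- it + 1L
    dev <- margin_deviation(w, memberships, margins)
  }
  structure(list(weights = as.numeric(w),
                 n_iterations = it,
                 converged = dev <= tol,
                 max_margin_deviation = dev),
            class = "raking_result")
}

#' @export
print.raking_result <- function(x, ...) {
  cat(sprintf("Raking result: %s after %d cycle(s), max margin deviation %.3g\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$max_margin_deviation))
  cat(sprintf("  weights: n = %d, sum = %.6g, range [%.4g, %.4g]\n",
              length(x$weights), sum(x$weights),
              min(x$weights), max(x$weights)))
  invisible(x)
}

#' Rake a population to margin tables
#'
#' Convenience wrapper around [ipf_rake()]: derives the membership columns
#' from the population via the margin variable definitions, calibrates the
#' `base_weight` column, and returns the population with a `weight` column
#' added.
#'
#' @param pop Filtered population data frame.
#' @param margins Margin table data frame (`variable`, `category`, `total`);
#'   variable names must be the `":"`-joined margin definitions used by
#'   [generate_margins()].
#' @param margin_vars The margin variable definitions (list of character
#'   vectors) matching `margins`.
#' @param ... Passed to [ipf_rake()] (`tol`, `max_iter`).
#' @return The population with calibrated `weight`; the raking result is
#'   attached as attribute `"raking"`.
#' @export
rake_population <- function(pop,
                            margins,
                            margin_vars = list(c("district", "gender"),
                                               "primary_ethnicity"),
                            ...) {
  mem <- margin_memberships(pop, margin_vars)
  res <- ipf_rake(pop$base_weight, mem, margins, ...)
  pop$weight <- res$weights
  attr(pop, "raking") <- res
  attr(pop, "config") <- attr(pop, "config")
  pop
}
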
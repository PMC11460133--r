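# Design-based estimation: Hajek mean, Taylor-linearised cluster-robust SE,
# t-based confidence intervals.

#' Hajek (ratio) weighted mean
#'
#' `sum(w * y) / sum(w)`.
#'
#' @param values Numeric vector.
#' @param weights Positive weights of the same length.
#' @return The weighted mean.
#' @export
weighted_mean <- function(values, weights) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (length(values) != length(weights))
    stop("values and weights must have equal length", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  sum(weights * values) / sum(weights)
}

#' Taylor-linearised cluster-robust standard error of the Hajek mean
#'
#' First-order linearisation of the ratio mean into per-unit scores
#' `z_i = w_i (y_i - ybar_w) / sum(w)`, aggregated to cluster (primary
#' sampling unit) totals `Z_c`, with the ultimate-cluster between-PSU
#' variance estimator `m/(m-1) * sum_c (Z_c - Zbar)^2` for `m` clusters.
#' Returns its square root. With equal weights and singleton clusters this
#' reduces to `sqrt(s^2 / n)` with `s^2` the usual sample variance.
#'
#' @inheritParams weighted_mean
#' @param cluster_ids Cluster (PSU) identifier per observation; at least two
#'   distinct clusters are required.
#' @return The standard error (non-negative scalar).
#' @export
linearised_se <- function(values, weights, cluster_ids) {
  if (length(values) != length(weights) ||
      length(values) != length(cluster_ids))
    stop("values, weights and cluster_ids must have equal length",
         call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  m <- length(unique(cluster_ids))
  if (m < 2)
    stop("degenerate design: need at least 2 clusters", call. = FALSE)
  ybar <- sum(weights * values) / sum(weights)
  z <- weights * (values - ybar) / sum(weights)
  zc <- rowsum(z, group = as.character(cluster_ids))
  v <- m / (m - 1) * sum((zc - mean(zc))^2)
  sqrt(v)
}

#' t-based confidence interval
#'
#' `mean +/- qt(1 - (1 - level)/2, df) * se`.
#'
#' @param mean Point estimate.
#' @param se Standard error (non-negative).
#' @param df Degrees of freedom (>= 1); the design convention is
#'   `n_clusters - 1`.
#' @param level Confidence level in (0, 1).
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @export
confidence_interval <- function(mean, se, df, level = 0.95) {
  if (level <= 0 || level >= 1)
    stop("level must lie in (0, 1)", call. = FALSE)
  if (se < 0) stop("se must be non-negative", call. = FALSE)
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  hw <- qt(1 - (1 - level) / 2, df) * se
  c(ci_low = mean - hw, ci_high = mean + hw)
}

#' Design-based mean with cluster-robust CI
#'
#' Combines [weighted_mean()], [linearised_se()] and [confidence_interval()]
#' into one survey estimate, with `df = n_clusters - 1`.
#'
#' @inheritParams linearised_se
#' @param level Confidence level.
#' @return An object of class `"survey_estimate"`: list with `mean`, `se`,
#'   `ci_low`, `ci_high`, `n`, `n_clusters`, `df`, `level`.
#' @export
svy_mean <- function(values, weights, cluster_ids, level = 0.95) {
  m <- length(unique(cluster_ids))
  mu <- weighted_mean(values, weights)
  se <- linearised_se(values, weights, cluster_ids)
  ci <- confidence_interval(mu, se, df = m - 1, level = level)
  structure(list(mean = mu, se = se,
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 n = length(values), n_clusters = m, df = m - 1,
                 level = level),
            class = "survey_estimate")
}

#' @export
print.survey_estimate <- function(x, ...) {
  cat(sprintf("%.4f (SE %.4f, %g%% CI %.4f to %.4f; n=%d, clusters=%d)\n",
              x$mean, x$se, 100 * x$level, x$ci_low, x$ci_high,
              x$n, x$n_clusters))
  invisible(x)
}

#' Summarise the five determinants
#'
#' One summary row per determinant: the weighted scheme gives the survey mean,
#' linearised cluster-robust SE and t-based CI; the unweighted scheme gives
#' the plain mean and SD (divisor `n - 1`).
#'
#' @param pop Filtered population data frame containing the determinant
#'   columns and `cluster_id`.
#' @param weights Weights to use for the weighted scheme; defaults to the
#'   `weight` column, falling back to `base_weight`.
#' @param scheme `"weighted"` or `"unweighted"`.
#' @param level Confidence level for the weighted scheme.
#' @return A `data.frame` with columns `determinant`, `scheme`, `n`, `mean`,
#'   and (weighted) `se`, `ci_low`, `ci_high`, `n_clusters`, `df` or
#'   (unweighted) `sd`.
#' @export
summarize_determinants <- function(pop, weights = NULL,
                                   scheme = c("weighted", "unweighted"),
                                   level = 0.95) {
  scheme <- match.arg(scheme)
  if (nrow(pop) == 0) stop("empty population", call. = FALSE)
  if (is.null(weights))
    weights <- if (!is.null(pop$weight)) pop$weight else pop$base_weight
  rows <- lapply(DETERMINANTS, function(d) {
    y <- pop[[d]]
    if (is.null(y)) stop(sprintf("determinant column '%s' missing", d),
                         call. = FALSE)
    if (scheme == "weighted") {
      est <- svy_mean(y, weights, pop$cluster_id, level = level)
      data.frame(determinant = d, scheme = scheme, n = est$n,
                 mean = est$mean, se = est$se,
                 ci_low = est$ci_low, ci_high = est$ci_high,
                 n_clusters = est$n_clusters, df = est$df,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(determinant = d, scheme = scheme, n = length(y),
                 mean = mean(y), sd = sd(y), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
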
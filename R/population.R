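#' Population configuration
#'
#' Build and validate the configuration that drives the synthetic survey
#' population generator. Defaults emulate a nationally representative
#' adolescent PA survey: 6,906 surveyed 12--17-year-olds of whom a proportion
#' `school_attendance_rate` attend secondary school (expected analytic sample
#' 5,035), with the sociodemographic composition of the analytic sample and
#' weighted baseline determinant means of 9.88 h/week PA, 3.15 settings, 4.93
#' types, 16.49 physical literacy and 21.19 social support.
#'
#' Categorical distributions (`age_distribution`, `gender_distribution`,
#' `deprivation_distribution`) must each sum to 1 within `1e-9`. Ethnicity is
#' multi-select: `ethnicity_rates` are independent marginal probabilities and
#' need not sum to 1; a participant whose draws are all zero is assigned
#' `european` so every participant has at least one ethnicity.
#'
#' @param n_surveyed Number of surveyed adolescents (positive integer).
#' @param school_attendance_rate Proportion attending secondary school or Kura
#'   Kaupapa, in (0, 1].
#' @param age_distribution Named proportions over ages `"12"`--`"17"`.
#' @param gender_distribution Named proportions over
#'   `c("male", "female", "diverse")`.
#' @param ethnicity_rates Named marginal probabilities per ethnicity label
#'   (multi-select; defaults `maori`, `european`, `pacific`, `asian`,
#'   `other`).
#' @param disability_rate Probability of reporting a physical disability.
#' @param deprivation_distribution Named proportions over
#'   `c("low", "mid", "high", "unknown")` (neighbourhood deprivation bands;
#'   deciles 1--3, 4--7, 8--10, missing).
#' @param pe_participation_by_age Named proportions per age giving the
#'   probability of taking physical education; default declines linearly from
#'   0.95 at age 12 to 0.35 at age 17.
#' @param n_districts Number of districts (clusters are nested in districts).
#' @param n_clusters Number of primary sampling units.
#' @param determinant_targets Named target means for the five determinants.
#' @param dispersion List of dispersion parameters: `pa_shape` (gamma shape
#'   for weekly hours), `settings_size` and `types_size` (checklist sizes for
#'   the binomial count models), `literacy_sd` and `support_sd` (latent
#'   normal SDs for the bounded scores).
#' @param score_bounds List with elements `physical_literacy` and
#'   `social_support`, each `c(min, max)`; defaults `c(4, 20)` and `c(5, 25)`
#'   (4 and 5 are the lowest codable values on these scales).
#' @param cluster_sd Named SDs of the cluster-level random intercept per
#'   determinant; default 1% of each target mean, small but non-zero so that
#'   cluster-robust variance estimation is non-degenerate.
#' @param determinant_shifts Optional sociodemographic effect-modification
#'   hooks: a list keyed by determinant, each a list with optional named
#'   numeric vectors `age` and/or `gender` of additive shifts applied to the
#'   generating mean.
#' @param base_weight Design weight assigned to every participant before
#'   raking (default 1: self-weighting sample).
#' @param seed Integer seed; generation is a pure function of the config.
#'
#' @return A list of class `"population_config"`.
#' @export
#' @examples
#' cfg <- population_config(n_surveyed = 500, seed = 1)
#' pop <- generate_population(cfg)
#' nrow(pop)
population_config <- function(n_surveyed = 6906,
                              school_attendance_rate = 5035 / 6906,
                              age_distribution = c(
                                "12" = 92, "13" = 981, "14" = 1253,
                                "15" = 1132, "16" = 922, "17" = 655) / 5035,
                              gender_distribution = c(
                                male = 2144, female = 2852, diverse = 39) / 5035,
                              ethnicity_rates = c(
                                maori = 694, european = 4253, pacific = 238,
                                asian = 574, other = 127) / 5035,
                              disability_rate = 308 / 5035,
                              deprivation_distribution = c(
                                low = 1867, mid = 1632, high = 725,
                                unknown = 811) / 5035,
                              pe_participation_by_age = setNames(
                                seq(0.95, 0.35, length.out = 6),
                                as.character(12:17)),
                              n_districts = 16,
                              n_clusters = 100,
                              determinant_targets = c(
                                pa_hours_week = 9.88, n_settings = 3.15,
                                n_types = 4.93, physical_literacy = 16.49,
                                social_support = 21.19),
                              dispersion = list(
                                pa_shape = 1.5, settings_size = 8,
                                types_size = 20, literacy_sd = 2.5,
                                support_sd = 2.5),
                              score_bounds = list(
                                physical_literacy = c(4, 20),
                                social_support = c(5, 25)),
                              cluster_sd = NULL,
                              determinant_shifts = NULL,
                              base_weight = 1,
                              seed = 1L) {
  if (!is.numeric(n_surveyed) || length(n_surveyed) != 1 || n_surveyed < 1 ||
      n_surveyed != round(n_surveyed))
    stop_field("n_surveyed", "must be a positive integer")
  if (!is.numeric(school_attendance_rate) ||
      school_attendance_rate <= 0 || school_attendance_rate > 1)
    stop_field("school_attendance_rate", "must lie in (0, 1]")
  check_simplex(age_distribution, "age_distribution")
  if (!setequal(names(age_distribution), as.character(12:17)))
    stop_field("age_distribution", "must be named over ages 12-17")
  check_simplex(gender_distribution, "gender_distribution")
  check_prob(ethnicity_rates, "ethnicity_rates")  # multi-select: no simplex
  if (is.null(names(ethnicity_rates)) || anyDuplicated(names(ethnicity_rates)))
    stop_field("ethnicity_rates", "must have unique names")
  check_prob(disability_rate, "disability_rate")
  check_simplex(deprivation_distribution, "deprivation_distribution")
  check_prob(pe_participation_by_age, "pe_participation_by_age")
  if (n_clusters < 1 || n_surveyed < n_clusters)
    stop_field("n_clusters", "need n_surveyed >= n_clusters >= 1")
  if (n_districts < 1 || n_clusters < n_districts)
    stop_field("n_districts", "need n_clusters >= n_districts >= 1")
  if (!all(DETERMINANTS %in% names(determinant_targets)))
    stop_field("determinant_targets", "must name all five determinants")
  if (any(determinant_targets <= 0))
    stop_field("determinant_targets", "target means must be positive")
  for (sc in c("physical_literacy", "social_support")) {
    b <- score_bounds[[sc]]
    if (is.null(b) || length(b) != 2 || b[1] >= b[2])
      stop_field("score_bounds", sprintf("%s needs c(min, max), min < max", sc))
    if (determinant_targets[[sc]] <= b[1] || determinant_targets[[sc]] >= b[2])
      stop_field("determinant_targets",
                 sprintf("%s target outside its score bounds", sc))
  }
  if (determinant_targets[["n_settings"]] > dispersion$settings_size)
    stop_field("dispersion", "settings_size below the n_settings target")
  if (determinant_targets[["n_types"]] > dispersion$types_size)
    stop_field("dispersion", "types_size below the n_types target")
  if (is.null(cluster_sd))
    cluster_sd <- 0.01 * determinant_targets[DETERMINANTS]
  if (any(cluster_sd < 0)) stop_field("cluster_sd", "must be non-negative")
  if (!is.numeric(base_weight) || base_weight <= 0)
    stop_field("base_weight", "must be positive")

  structure(list(
    n_surveyed = as.integer(n_surveyed),
    school_attendance_rate = school_attendance_rate,
    age_distribution = age_distribution[as.character(12:17)],
    gender_distribution = gender_distribution[c("male", "female", "diverse")],
    ethnicity_rates = ethnicity_rates,
    disability_rate = disability_rate,
    deprivation_distribution =
      deprivation_distribution[c("low", "mid", "high", "unknown")],
    pe_participation_by_age = pe_participation_by_age[as.character(12:17)],
    n_districts = as.integer(n_districts),
    n_clusters = as.integer(n_clusters),
    determinant_targets = determinant_targets[DETERMINANTS],
    dispersion = dispersion,
    score_bounds = score_bounds,
    cluster_sd = setNames(as.numeric(cluster_sd[DETERMINANTS]), DETERMINANTS),
    determinant_shifts = determinant_shifts,
    base_weight = base_weight,
    seed = as.integer(seed)
  ), class = "population_config")
}

# Latent mean of a truncated normal on [a, b] with latent sd `sigma` solved so
# the truncated mean equals `target`.
solve_truncnorm_mu <- function(target, sigma, a, b) {
  tmean <- function(mu) {
    al <- (a - mu) / sigma; be <- (b - mu) / sigma
    z <- pnorm(be) - pnorm(al)
    mu + sigma * (dnorm(al) - dnorm(be)) / z
  }
  # tmean is increasing in mu; targets strictly inside (a, b) that are not
  # reachable within [a, b] are bracketed by widening one side.
  lo <- a; hi <- b
  while (tmean(lo) > target && lo > a - 20 * sigma) lo <- lo - sigma
  while (tmean(hi) < target && hi < b + 20 * sigma) hi <- hi + sigma
  uniroot(function(mu) tmean(mu) - target, lower = lo, upper = hi,
          tol = 1e-12)$root
}

# Draw truncated normals on [a, b]; mu may be a vector.
rtruncnorm <- function(n, mu, sigma, a, b) {
  lo <- pnorm(a, mu, sigma)
  hi <- pnorm(b, mu, sigma)
  qnorm(runif(n, lo, hi), mu, sigma)
}

#' Generate a synthetic survey population
#'
#' Draws `config$n_surveyed` participants with independent sociodemographics
#' (multi-select ethnicity as independent Bernoulli indicators), a cluster
#' design (`n_clusters` primary sampling units nested round-robin in
#' `n_districts` districts), school attendance and PE participation flags, and
#' the five determinant outcomes. Determinants are generated as: gamma for
#' weekly PA hours; binomial checklist counts for settings and types; and
#' bound-truncated normals for the physical literacy and social support
#' scores, each centred (via a solved latent mean for the truncated scores) on
#' the configured target plus a small cluster-level random intercept.
#'
#' Generation is deterministic in `(config, config$seed)` and leaves the
#' caller's RNG state untouched.
#'
#' @param config A [population_config()].
#' @return A `data.frame` with one row per participant and columns `id`,
#'   `district`, `cluster_id`, `age`, `gender`, `eth_<label>` indicator
#'   columns, `disability`, `deprivation`, `attends_school`, `takes_pe`,
#'   `base_weight`, and the five determinant columns (see
#'   [determinant_names()]). The config is attached as attribute `"config"`.
#' @export
generate_population <- function(config) {
  if (!inherits(config, "population_config"))
    config <- do.call(population_config, config)
  n <- config$n_surveyed
  with_seed(config$seed, {
    cluster <- sample.int(config$n_clusters, n, replace = TRUE)
    district <- (cluster - 1L) %% config$n_districts + 1L
    age <- as.integer(sample(names(config$age_distribution), n, replace = TRUE,
                             prob = config$age_distribution))
    gender <- sample(names(config$gender_distribution), n, replace = TRUE,
                     prob = config$gender_distribution)
    eth <- vapply(config$ethnicity_rates,
                  function(p) runif(n) < p, logical(n))  # n x labels
    if (!is.matrix(eth))
      eth <- matrix(eth, nrow = n,
                    dimnames = list(NULL, names(config$ethnicity_rates)))
    none <- rowSums(eth) == 0
    if (any(none)) {
      if (!"european" %in% colnames(eth))
        eth <- cbind(eth, european = FALSE)
      eth[none, "european"] <- TRUE
    }
    disability <- runif(n) < config$disability_rate
    deprivation <- sample(names(config$deprivation_distribution), n,
                          replace = TRUE,
                          prob = config$deprivation_distribution)
    attends <- runif(n) < config$school_attendance_rate
    takes_pe <- runif(n) < config$pe_participation_by_age[as.character(age)]

    pop <- data.frame(
      id = sprintf("P%06d", seq_len(n)),
      district = sprintf("D%02d", district),
      cluster_id = sprintf("C%03d", cluster),
      age = age, gender = gender,
      stringsAsFactors = FALSE
    )
    eth_df <- as.data.frame(eth)
    names(eth_df) <- paste0("eth_", names(eth_df))
    pop <- cbind(pop, eth_df)
    pop$disability <- disability
    pop$deprivation <- deprivation
    pop$attends_school <- attends
    pop$takes_pe <- takes_pe
    pop$base_weight <- rep(config$base_weight, n)

    tg <- config$determinant_targets
    dsp <- config$dispersion
    # Cluster random intercepts, one per determinant.
    ri <- vapply(DETERMINANTS, function(d)
      rnorm(config$n_clusters, 0, config$cluster_sd[[d]]),
      numeric(config$n_clusters))
    if (!is.matrix(ri))
      ri <- matrix(ri, nrow = config$n_clusters,
                   dimnames = list(NULL, DETERMINANTS))

    shift_for <- function(det) {
      s <- rep(0, n)
      h <- config$determinant_shifts[[det]]
      if (!is.null(h$age)) {
        v <- h$age[as.character(age)]
        s <- s + ifelse(is.na(v), 0, v)
      }
      if (!is.null(h$gender)) {
        v <- h$gender[gender]
        s <- s + ifelse(is.na(v), 0, v)
      }
      s
    }

    mu_pa <- pmax(tg[["pa_hours_week"]] + ri[cluster, "pa_hours_week"] +
                    shift_for("pa_hours_week"), 0.1)
    pop$pa_hours_week <- rgamma(n, shape = dsp$pa_shape,
                                scale = mu_pa / dsp$pa_shape)

    p_set <- pmin(pmax((tg[["n_settings"]] + ri[cluster, "n_settings"] +
                          shift_for("n_settings")) / dsp$settings_size,
                       0), 1)
    # counts stored as numeric so scenario arithmetic never retypes columns
    pop$n_settings <- as.numeric(rbinom(n, dsp$settings_size, p_set))

    p_typ <- pmin(pmax((tg[["n_types"]] + ri[cluster, "n_types"] +
                          shift_for("n_types")) / dsp$types_size, 0), 1)
    pop$n_types <- as.numeric(rbinom(n, dsp$types_size, p_typ))

    bl <- config$score_bounds$physical_literacy
    mu0 <- solve_truncnorm_mu(tg[["physical_literacy"]], dsp$literacy_sd,
                              bl[1], bl[2])
    pop$physical_literacy <- rtruncnorm(
      n, mu0 + ri[cluster, "physical_literacy"] + shift_for("physical_literacy"),
      dsp$literacy_sd, bl[1], bl[2])

    bs <- config$score_bounds$social_support
    mu0 <- solve_truncnorm_mu(tg[["social_support"]], dsp$support_sd,
                              bs[1], bs[2])
    pop$social_support <- rtruncnorm(
      n, mu0 + ri[cluster, "social_support"] + shift_for("social_support"),
      dsp$support_sd, bs[1], bs[2])

    attr(pop, "config") <- config
    pop
  })
}

#' Restrict to school attendees
#'
#' Keeps exactly the participants with `attends_school = TRUE`, preserving
#' order (the analytic sample: secondary school or Kura Kaupapa attendees).
#'
#' @param pop Population data frame from [generate_population()].
#' @return The filtered data frame; the `"config"` attribute is carried over.
#' @export
apply_school_filter <- function(pop) {
  if (is.null(pop$attends_school))
    stop("column 'attends_school' is missing", call. = FALSE)
  out <- pop[pop$attends_school, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- attr(pop, "config")
  out
}

#' Derive a single-select primary ethnic group
#'
#' Raking margins need mutually exclusive categories, but ethnicity is
#' multi-select. This collapses the `eth_*` indicators by the prioritised
#' output convention used for NZ ethnicity reporting:
#' Maori > Pacific > Asian > Other > European.
#'
#' @param pop Population data frame with `eth_*` indicator columns.
#' @return Character vector of primary ethnic group per participant.
#' @export
primary_ethnicity <- function(pop) {
  priority <- c("maori", "pacific", "asian", "other", "european")
  cols <- paste0("eth_", priority)
  cols <- cols[cols %in% names(pop)]
  if (length(cols) == 0)
    stop("no eth_* indicator columns found", call. = FALSE)
  out <- rep(NA_character_, nrow(pop))
  for (cl in rev(cols)) out[pop[[cl]]] <- sub("^eth_", "", cl)
  if (anyNA(out))
    stop("participants with empty ethnicity set", call. = FALSE)
  out
}

# Membership data frame for a list of margin variable definitions. Each
# definition is a character vector of columns; composites are joined with
# ":". "primary_ethnicity" is derived on the fly.
margin_memberships <- function(pop, margin_vars) {
  out <- lapply(margin_vars, function(vars) {
    vals <- lapply(vars, function(v) {
      if (v == "primary_ethnicity") return(primary_ethnicity(pop))
      if (!v %in% names(pop))
        stop(sprintf("margin variable '%s' not in population schema", v),
             call. = FALSE)
      as.character(pop[[v]])
    })
    do.call(paste, c(vals, sep = ":"))
  })
  names(out) <- vapply(margin_vars, paste, "", collapse = ":")
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Build raking margin tables from a population
#'
#' Tabulates each margin variable (or composite of variables) on the supplied
#' population and scales the counts by `scale`, yielding the "known
#' population" totals that raking calibrates to. Every margin table sums to
#' the same grand total `T = nrow(pop) * scale`.
#'
#' @param pop Filtered population data frame.
#' @param margin_vars List of character vectors of column names; the special
#'   name `"primary_ethnicity"` uses [primary_ethnicity()]. Default: district
#'   by gender, and primary ethnic group.
#' @param scale Positive scale factor applied to observed counts.
#' @return A `data.frame` with columns `variable`, `category`, `total`.
#' @export
generate_margins <- function(pop,
                             margin_vars = list(c("district", "gender"),
                                                "primary_ethnicity"),
                             scale = 1) {
  if (nrow(pop) == 0) stop("empty population", call. = FALSE)
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  mem <- margin_memberships(pop, margin_vars)
  tabs <- lapply(names(mem), function(v) {
    tb <- table(mem[[v]])
    data.frame(variable = v, category = names(tb),
               total = as.numeric(tb) * scale,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Read and write population microdata CSV
#'
#' RFC-4180 CSV round trip for the population table (UTF-8, header row,
#' logical columns written as TRUE/FALSE).
#'
#' @param pop Population data frame.
#' @param path File path.
#' @return `write_population_csv` returns `path` invisibly;
#'   `read_population_csv` returns the data frame.
#' @export
write_population_csv <- function(pop, path) {
  write.csv(pop, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' @rdname write_population_csv
#' @param margins Margin table data frame (`variable`, `category`, `total`).
#' @export
write_margins_csv <- function(margins, path) {
  write.csv(margins, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_margins_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
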
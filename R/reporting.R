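# Reporting: demographic table, full disk-writing pipeline, run manifest.

#' Sociodemographic composition table
#'
#' Counts and percentages (one decimal, half-up) by age, gender, ethnicity
#' (multi-select indicators, so ethnicity percentages may exceed 100% in
#' total), physical disability and deprivation band.
#'
#' @param pop Filtered population data frame.
#' @return A `data.frame` with columns `variable`, `category`, `n`, `pct`.
#' @export
demographic_table <- function(pop) {
  N <- nrow(pop)
  pct <- function(n) round_half_up(100 * n / N, 1)
  rows <- list()
  add <- function(variable, category, n)
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, category = as.character(category),
      n = as.integer(n), pct = pct(n), stringsAsFactors = FALSE)
  for (a in sort(unique(pop$age))) add("age", a, sum(pop$age == a))
  for (g in c("male", "female", "diverse"))
    add("gender", g, sum(pop$gender == g))
  eth_cols <- grep("^eth_", names(pop), value = TRUE)
  for (cl in eth_cols)
    add("ethnicity", sub("^eth_", "", cl), sum(pop[[cl]]))
  add("disability", "yes", sum(pop$disability))
  for (dp in c("low", "mid", "high", "unknown"))
    add("deprivation", dp, sum(pop$deprivation == dp))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Read a run config from YAML or JSON; returns a plain list.
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

# Coerce the population section of a run config into a population_config.
config_from_list <- function(lst) {
  if (is.null(lst)) return(population_config())
  args <- lst
  for (nm in c("age_distribution", "gender_distribution", "ethnicity_rates",
               "deprivation_distribution", "pe_participation_by_age",
               "determinant_targets", "cluster_sd"))
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  if (!is.null(args$score_bounds))
    args$score_bounds <- lapply(args$score_bounds, unlist)
  do.call(population_config, args)
}

#' Run the full pipeline and write all outputs
#'
#' Executes generate -> school filter -> rake -> baseline estimates ->
#' per-intervention scenarios -> scorecard -> costs, writing CSV tables, an
#' SVG estimates figure and a JSON run manifest (seed, config hash, package
#' and R versions, row counts) to `out_dir`. Identical config and seed yield
#' byte-identical tables. On any stage error the partial outputs written so
#' far are removed and the error names the failed stage.
#'
#' @param config A [population_config()], a list with elements `population`
#'   (list of [population_config()] arguments), optional `margin_scale`,
#'   `level`, `interventions` (`"calibrated"`/`"illustrative"`), `n_schools`,
#'   `students_per_school`, `seed` -- or a path to a YAML/JSON file with that
#'   structure.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage log lines.
#' @return The fitted [scenario_model()], invisibly; attribute `"files"`
#'   lists the written paths.
#' @export
run_pipeline <- function(config = population_config(), out_dir, quiet = FALSE) {
  if (is.character(config) && length(config) == 1)
    config <- read_run_config(config)
  if (inherits(config, "population_config"))
    config <- list(population = config)
  interventions <- if (is.null(config$interventions)) "calibrated"
                   else config$interventions
  margin_scale <- if (is.null(config$margin_scale)) 55 else config$margin_scale
  level <- if (is.null(config$level)) 0.95 else config$level
  n_schools <- if (is.null(config$n_schools)) 376 else config$n_schools
  sps <- if (is.null(config$students_per_school)) 740
         else config$students_per_school

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  stage <- "setup"
  log <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  emit <- function(obj, file) {
    path <- file.path(out_dir, file)
    write.csv(obj, path, row.names = FALSE, fileEncoding = "UTF-8")
    written <<- c(written, path)
    path
  }

  model <- tryCatch({
    stage <- "config"
    pc <- if (inherits(config$population, "population_config"))
      config$population else config_from_list(config$population)
    if (!is.null(config$seed)) pc$seed <- as.integer(config$seed)

    stage <- "model fit"
    m <- scenario_model(pc, interventions = interventions,
                        margin_scale = margin_scale, level = level,
                        n_schools = n_schools, students_per_school = sps)
    log("stage model fit: %d participants in, %d analytic rows out",
        pc$n_surveyed, nrow(m$population))

    stage <- "tables"
    emit(m$population, "population.csv")
    emit(m$margins, "margins.csv")
    emit(demographic_table(m$population), "demographics.csv")
    emit(m$baseline, "baseline_estimates.csv")
    emit(m$baseline_unweighted, "baseline_unweighted.csv")
    for (nm in names(m$scenarios)) {
      s <- m$scenarios[[nm]]
      emit(data.frame(intervention = nm, s$table,
                      eligible_weight_share = s$eligible_weight_share),
           sprintf("scenario_%s.csv", nm))
    }
    if (!is.null(m$scorecard))
      emit(data.frame(determinant = rownames(m$scorecard),
                      unclass(m$scorecard)), "scorecard.csv")
    if (!is.null(m$costs)) emit(m$costs, "costs.csv")
    log("stage tables: %d files", length(written))

    stage <- "figure"
    fig <- file.path(out_dir, "estimates.svg")
    svg(fig, width = 10, height = 7)
    plot(m)
    dev.off()
    written <- c(written, fig)

    stage <- "manifest"
    cfg_json <- jsonlite::toJSON(unclass(pc), auto_unbox = TRUE, digits = NA)
    manifest <- list(
      seed = pc$seed,
      config_hash = config_hash(as.character(cfg_json)),
      package_version = as.character(packageVersion("schoolPA")),
      r_version = R.version.string,
      n_surveyed = pc$n_surveyed,
      n_analytic = nrow(m$population),
      interventions = names(m$scenarios),
      files = basename(written)
    )
    mpath <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, mpath)
    log("stage manifest: written")
    m
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  attr(model, "files") <- written
  invisible(model)
}
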
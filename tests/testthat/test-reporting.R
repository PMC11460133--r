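# Build a population whose gender counts equal the published analytic sample
# so the percentage rounding rule can be checked against known values.
published_gender_pop <- function() {
  n <- 5035
  pop <- data.frame(
    age = rep(12L, n),
    gender = rep(c("male", "female", "diverse"), c(2144, 2852, 39)),
    eth_european = TRUE,
    disability = FALSE,
    deprivation = "low",
    stringsAsFactors = FALSE)
  pop
}

test_that("demographic percentages follow the one-decimal half-up rule", {
  tab <- demographic_table(published_gender_pop())
  g <- tab[tab$variable == "gender", ]
  expect_equal(g$n[g$category == "female"], 2852L)
  expect_equal(g$pct[g$category == "female"], 56.6)
  expect_equal(g$pct[g$category == "male"], 42.6)
  expect_equal(g$pct[g$category == "diverse"], 0.8)
  # empty categories report 0 (0.0)
  expect_equal(g$n[g$category == "diverse"], 39L)
  d <- tab[tab$variable == "deprivation", ]
  expect_equal(d$n[d$category == "high"], 0L)
  expect_equal(d$pct[d$category == "high"], 0)
  # every percentage equals the rounding rule applied to its own count
  expect_equal(tab$pct, sign(tab$n) * floor(abs(100 * tab$n / 5035) * 10 +
                                              0.5 + 1e-9) / 10)
})

test_that("the scenario model bundles every pipeline stage", {
  m <- scenario_model(population_config(n_surveyed = 1200, n_clusters = 40,
                                        n_districts = 8, seed = 5),
                      margin_scale = 10)
  expect_s3_class(m, "scenario_model")
  expect_true(m$raking$converged)
  expect_equal(nrow(m$baseline), 5)
  expect_named(m$scenarios, c("TAPE", "PL", "PAL", "NE"))
  expect_equal(dim(m$scorecard), c(5L, 4L))
  for (i in 1:5) expect_setequal(m$scorecard[i, ], 1:4)
  expect_equal(nrow(m$costs), 4)
  expect_equal(unname(coef(m)["pa_hours_week", "NE"]), 0.2, tolerance = 1e-9)
  expect_output(print(m), "analytic sample")
  expect_output(print(summary(m)), "scorecard|Scorecard|scenario",
                ignore.case = TRUE)
})

test_that("run_pipeline writes the full artifact bundle deterministically", {
  cfg <- list(population = list(n_surveyed = 900, n_clusters = 30,
                                n_districts = 6, seed = 9),
              margin_scale = 5)
  d1 <- file.path(tempdir(), "run1"); d2 <- file.path(tempdir(), "run2")
  m <- run_pipeline(cfg, d1, quiet = TRUE)
  run_pipeline(cfg, d2, quiet = TRUE)
  files <- basename(attr(m, "files"))
  expect_true(all(c("population.csv", "margins.csv", "demographics.csv",
                    "baseline_estimates.csv", "scorecard.csv", "costs.csv",
                    "manifest.json") %in% files))
  expect_length(grep("^scenario_", files), 4)
  sc <- read.csv(file.path(d1, "scorecard.csv"))
  expect_equal(dim(sc), c(5L, 5L))
  expect_equal(nrow(read.csv(file.path(d1, "costs.csv"))), 4)
  # byte-identical CSV outputs for identical config + seed
  for (f in grep("\\.csv$", files, value = TRUE))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$seed, 9)
  expect_true(nzchar(man$config_hash))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a zero-intervention config yields baseline-only outputs", {
  d <- file.path(tempdir(), "run0")
  m <- run_pipeline(list(population = list(n_surveyed = 600, n_clusters = 20,
                                           n_districts = 4, seed = 2),
                         interventions = list(), margin_scale = 2),
                    d, quiet = TRUE)
  files <- basename(attr(m, "files"))
  expect_true("baseline_estimates.csv" %in% files)
  expect_length(grep("^scenario_", files), 0)
  expect_false("scorecard.csv" %in% files)
  unlink(d, recursive = TRUE)
})

test_that("YAML run configs are read and drive the pipeline", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("population:",
               "  n_surveyed: 500",
               "  n_clusters: 20",
               "  n_districts: 4",
               "  seed: 4",
               "margin_scale: 3",
               "interventions: illustrative"), yml)
  d <- file.path(tempdir(), "runyml")
  m <- run_pipeline(yml, d, quiet = TRUE)
  expect_equal(nrow(m$population), sum(m$population$attends_school))
  expect_named(m$scenarios, c("TAPE", "PL", "PAL", "NE"))
  unlink(d, recursive = TRUE); unlink(yml)
})

test_that("pipeline errors name the failing stage and clean up outputs", {
  d <- file.path(tempdir(), "runbad")
  expect_error(run_pipeline(list(population = list(n_surveyed = 100,
                                                   n_clusters = 200)),
                            d, quiet = TRUE),
               "stage 'config'")
  expect_length(list.files(d), 0)
  unlink(d, recursive = TRUE)
})

test_that("the estimates figure renders for full and degenerate inputs", {
  m <- scenario_model(population_config(n_surveyed = 800, n_clusters = 20,
                                        n_districts = 4, seed = 8),
                      margin_scale = 2)
  f <- tempfile(fileext = ".svg")
  grDevices::svg(f); plot(m); grDevices::dev.off()
  expect_true(file.exists(f) && file.size(f) > 0)
  # zero-width CIs (se = 0) render without error
  m$baseline$ci_low <- m$baseline$ci_high <- m$baseline$mean
  for (nm in names(m$scenarios)) {
    t <- m$scenarios[[nm]]$table
    t$post_ci_low <- t$post_ci_high <- t$post_mean
    m$scenarios[[nm]]$table <- t
  }
  f2 <- tempfile(fileext = ".svg")
  grDevices::svg(f2); expect_no_error(plot(m)); grDevices::dev.off()
  unlink(c(f, f2))
})
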
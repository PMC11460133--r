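# Independent oracles and small fixtures used across the suite.

# Brute-force raking oracle: category-by-category multiplicative updates,
# written independently of ipf_rake (per-category sequential scaling).
bf_rake <- function(w, mem, margins_list, cycles = 5000) {
  for (i in seq_len(cycles)) {
    for (v in names(margins_list)) {
      tot <- margins_list[[v]]
      for (cat in names(tot)) {
        idx <- mem[[v]] == cat
        w[idx] <- w[idx] * tot[[cat]] / sum(w[idx])
      }
    }
  }
  w
}

# Margin list -> the data.frame format the package consumes.
margins_df <- function(margins_list) {
  do.call(rbind, lapply(names(margins_list), function(v)
    data.frame(variable = v, category = names(margins_list[[v]]),
               total = as.numeric(margins_list[[v]]),
               stringsAsFactors = FALSE)))
}

# Cluster bootstrap SE of the Hajek mean (resample clusters with
# replacement).
cluster_bootstrap_se <- function(y, w, cl, B = 5000, seed = 42) {
  cl <- as.character(cl)
  ids <- unique(cl)
  sw <- rowsum(w, cl)[ids, ]
  swy <- rowsum(w * y, cl)[ids, ]
  set.seed(seed)
  reps <- replicate(B, {
    pick <- sample.int(length(ids), replace = TRUE)
    sum(swy[pick]) / sum(sw[pick])
  })
  sd(reps)
}

# Minimal population fixture with all schema columns, deterministic.
make_test_pop <- function(n = 60, seed = 99) {
  set.seed(seed)
  pop <- data.frame(
    id = sprintf("T%03d", seq_len(n)),
    district = sprintf("D%02d", sample(1:4, n, TRUE)),
    cluster_id = sprintf("C%02d", sample(1:8, n, TRUE)),
    age = sample(12:17, n, TRUE),
    gender = sample(c("male", "female", "diverse"), n, TRUE,
                    prob = c(0.45, 0.45, 0.1)),
    eth_maori = runif(n) < 0.2,
    eth_european = TRUE,
    disability = runif(n) < 0.1,
    deprivation = sample(c("low", "mid", "high", "unknown"), n, TRUE),
    attends_school = TRUE,
    takes_pe = runif(n) < 0.6,
    base_weight = runif(n, 0.5, 2),
    stringsAsFactors = FALSE
  )
  pop$pa_hours_week <- rgamma(n, 2, scale = 5)
  pop$n_settings <- as.numeric(rbinom(n, 8, 0.4))
  pop$n_types <- as.numeric(rbinom(n, 20, 0.25))
  pop$physical_literacy <- runif(n, 4, 20)
  pop$social_support <- runif(n, 5, 25)
  pop
}

default_filtered_pop <- function(seed = 1, n = 6906) {
  apply_school_filter(generate_population(
    population_config(n_surveyed = n, seed = seed)))
}
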
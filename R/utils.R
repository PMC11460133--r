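# Internal helpers shared across modules.

# Round half-up at `digits` decimal places (reporting convention for
# percentages and currency; base round() is half-to-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Round half away from zero to an integer (used when clamping count
# determinants after a relative effect).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5 + 1e-9)

stop_field <- function(field, msg) {
  stop(sprintf("configuration error in '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_field(field, "all values must be proportions in [0, 1]")
  invisible(x)
}

check_simplex <- function(x, field, tol = 1e-9) {
  check_prob(x, field)
  if (abs(sum(x) - 1) > tol)
    stop_field(field, sprintf("proportions must sum to 1 (got %.12f)", sum(x)))
  invisible(x)
}

# Polynomial rolling hash of a character scalar; used for the run manifest's
# config fingerprint (no external digest dependency).
config_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
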
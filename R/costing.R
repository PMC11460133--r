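# Cost conversion to NZD 2019 via CPI (within source currency) then PPP, and
# per-school / per-student / national rollout arithmetic.

#' CPI inflation adjustment within a currency
#'
#' `amount * cpi[currency, to_year] / cpi[currency, from_year]`.
#'
#' @param amount Positive amount in `currency`.
#' @param currency ISO-4217 currency code.
#' @param from_year,to_year Calendar years present in the series.
#' @param cpi CPI series: `data.frame(currency, year, index)` with positive
#'   indices.
#' @return The adjusted amount.
#' @export
cpi_adjust <- function(amount, currency, from_year, to_year, cpi) {
  idx <- function(yr) {
    v <- cpi$index[cpi$currency == currency & cpi$year == yr]
    if (length(v) != 1 || v <= 0)
      stop(sprintf("CPI series has no entry for (%s, %d)", currency, yr),
           call. = FALSE)
    v
  }
  from <- idx(from_year)
  amount * idx(to_year) / from
}

#' PPP conversion to NZD
#'
#' `amount / ppp[currency]` where the PPP factor is units of `currency` per
#' NZD at purchasing-power parity.
#'
#' @param amount Amount in `currency`.
#' @param currency ISO-4217 currency code.
#' @param ppp PPP table: `data.frame(currency, factor_per_nzd)` with positive
#'   factors and `NZD = 1`.
#' @return The amount in NZD.
#' @export
ppp_convert <- function(amount, currency, ppp) {
  f <- ppp$factor_per_nzd[ppp$currency == currency]
  if (length(f) != 1 || f <= 0)
    stop(sprintf("PPP table has no factor for %s", currency), call. = FALSE)
  amount / f
}

#' Convert cost components to a per-school NZD amount
#'
#' Each component is CPI-adjusted within its source currency from its source
#' year to `target_year`, then PPP-converted to NZD; components are summed.
#' If `basis` is `list(type = "total_for_n_schools", n = k)` the sum is
#' divided by `k`. The fixed order of operations is CPI first, then PPP.
#'
#' @param components `data.frame(label, amount, currency, year)`; amounts
#'   positive.
#' @param cpi CPI series (see [cpi_adjust()]); defaults to the shipped
#'   synthetic calibration series.
#' @param ppp PPP table (see [ppp_convert()]); defaults to the shipped
#'   synthetic calibration table.
#' @param target_year Target year (default 2019).
#' @param basis `"per_school"` or `list(type = "total_for_n_schools", n = k)`.
#' @return Per-school cost in NZD at `target_year` prices.
#' @export
cost_to_nzd <- function(components, cpi = default_cpi(), ppp = default_ppp(),
                        target_year = 2019, basis = "per_school") {
  if (any(components$amount <= 0))
    stop("cost component amounts must be positive", call. = FALSE)
  nzd <- mapply(function(a, cur, yr) {
    infl <- cpi_adjust(a, cur, yr, target_year, cpi)
    ppp_convert(infl, cur, ppp)
  }, components$amount, components$currency, components$year)
  total <- sum(nzd)
  if (is.list(basis) && identical(basis$type, "total_for_n_schools"))
    total <- total / basis$n
  total
}

#' Per-student cost
#'
#' Per-school cost divided by the average number of secondary students per
#' school, rounded half-up to the cent.
#'
#' @param per_school_nzd Per-school cost in NZD.
#' @param students_per_school Average students per school (default 740).
#' @return Per-student cost in NZD, to the cent.
#' @export
per_student_cost <- function(per_school_nzd, students_per_school = 740) {
  if (students_per_school < 1)
    stop("students_per_school must be >= 1", call. = FALSE)
  round_half_up(per_school_nzd / students_per_school, 2)
}

#' National rollout cost
#'
#' Per-school cost times the number of secondary schools nationwide.
#'
#' @param per_school_nzd Per-school cost in NZD.
#' @param n_schools Number of schools (default 376).
#' @return National rollout cost in NZD.
#' @export
national_rollout_cost <- function(per_school_nzd, n_schools = 376) {
  if (n_schools < 1) stop("n_schools must be >= 1", call. = FALSE)
  per_school_nzd * n_schools
}

#' Full costing for one intervention
#'
#' Converts the intervention's cost components to per-school NZD at
#' `target_year` prices and derives per-student and national rollout costs.
#'
#' @param spec An [intervention_spec()] with `cost_inputs`, or a component
#'   `data.frame(label, amount, currency, year)`.
#' @inheritParams cost_to_nzd
#' @param n_schools Number of secondary schools (default 376).
#' @param students_per_school Average students per school (default 740).
#' @return An object of class `"cost_result"`: list with `per_school_nzd`,
#'   `per_student_nzd` (rounded to the cent), `national_nzd`, `n_schools`,
#'   `students_per_school`.
#' @export
cost_intervention <- function(spec, cpi = default_cpi(), ppp = default_ppp(),
                              target_year = 2019, n_schools = 376,
                              students_per_school = 740) {
  if (inherits(spec, "intervention_spec")) {
    components <- spec$cost_inputs
    basis <- spec$basis
    name <- spec$name
  } else {
    components <- spec
    basis <- "per_school"
    name <- NA_character_
  }
  if (is.null(components)) stop("no cost inputs", call. = FALSE)
  per_school <- cost_to_nzd(components, cpi, ppp, target_year, basis)
  structure(list(intervention = name,
                 per_school_nzd = per_school,
                 per_student_nzd = per_student_cost(per_school,
                                                    students_per_school),
                 national_nzd = national_rollout_cost(per_school, n_schools),
                 n_schools = n_schools,
                 students_per_school = students_per_school),
            class = "cost_result")
}

#' @export
print.cost_result <- function(x, ...) {
  cat(sprintf("%s: per school NZD %.2f | per student NZD %.2f | national NZD %.2f (%d schools)\n",
              if (is.na(x$intervention)) "cost" else x$intervention,
              x$per_school_nzd, x$per_student_nzd, x$national_nzd,
              x$n_schools))
  invisible(x)
}

#' Consistency check between per-school and printed per-student costs
#'
#' Recomputes the per-student cost from the per-school cost and compares with
#' a printed per-student figure. Used to surface the documented NE
#' inconsistency (88,755 / 740 = 119.94, printed 119.40) rather than silently
#' matching it.
#'
#' @param per_school_nzd Per-school cost in NZD.
#' @param printed_per_student The printed per-student figure to check.
#' @param students_per_school Average students per school.
#' @param tol Tolerance in dollars (default half a cent).
#' @return List with `computed`, `printed`, `consistent`, `difference`.
#' @export
check_cost_consistency <- function(per_school_nzd, printed_per_student,
                                   students_per_school = 740, tol = 0.005) {
  computed <- per_student_cost(per_school_nzd, students_per_school)
  list(computed = computed, printed = printed_per_student,
       consistent = abs(computed - printed_per_student) <= tol,
       difference = computed - printed_per_student)
}

#' Shipped synthetic CPI and PPP calibration tables
#'
#' Small editable tables covering the currencies and years of the shipped
#' intervention presets. They are synthetic calibration values, back-solved
#' so that the CPI-then-PPP pipeline reproduces the published per-school
#' NZD-2019 figures from the published source amounts; they are not official
#' OECD statistics. Supply real OECD series for any other conversion.
#'
#' @return `default_cpi()`: `data.frame(currency, year, index)`;
#'   `default_ppp()`: `data.frame(currency, factor_per_nzd, reference_year)`.
#' @export
default_cpi <- function() {
  read.csv(system.file("extdata", "cpi_synthetic.csv", package = "schoolPA"),
           stringsAsFactors = FALSE)
}

#' @rdname default_cpi
#' @export
default_ppp <- function() {
  read.csv(system.file("extdata", "ppp_synthetic.csv", package = "schoolPA"),
           stringsAsFactors = FALSE)
}
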
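# Canonical gross drug budget-impact engine:
# eligible population -> treated person-years -> packs -> annual cost.
# Deliberately multiplicative and monotone in every parameter, which is what
# the corner-enumeration oracle in the PSA relies on.

extra_product <- function(spec, category) {
  ex <- spec$extra_parameters
  v <- ex$value[ex$category == category]
  if (length(v)) prod(v) else 1
}

#' Eligible patient population in a model year
#'
#' The source population is the prevalent pool plus the annual incident
#' inflow (whichever features are on), compounded by the growth rate and
#' multiplied through any extra population attrition fractions:
#' `(pool + inflow) * (1 + g)^(year - 1) * prod(factors)`.
#'
#' @param spec A [bia_spec()].
#' @param year 1-based model year (vectorised), `1 <= year <= horizon_years`.
#' @return Persons eligible in each requested year.
#' @examples
#' spec <- bia_spec("A", prevalent_pool = 1000, market_share = 0.1,
#'                  units_per_day = 1, pack_size = 30, list_price = 100)
#' eligible_population(spec, 1)
#' @export
eligible_population <- function(spec, year) {
  validate_bia_spec(spec)
  check_year(spec, year)
  eligible_population_(spec)[year]
}

check_year <- function(spec, year) {
  if (any(year < 1 | year > spec$horizon_years | year != floor(year))) {
    abort(sprintf("year must be an integer in 1..%d", spec$horizon_years))
  }
}

eligible_population_ <- function(spec) {
  f <- spec$features
  base <- spec$prevalent_pool * f[["prevalence"]] +
    spec$incident_inflow * f[["incidence"]]
  years <- seq_len(spec$horizon_years)
  out <- base * (1 + spec$growth_rate)^(years - 1) *
    extra_product(spec, "population")
  if (any(out < 0)) abort("invariant violation: negative eligible population")
  out
}

#' Person-years on treatment in a model year
#'
#' Market share is point-in-year penetration: in the simple case (no
#' discontinuation, unbounded duration) treated person-years in year y are
#' `eligible(y) * share[y]`. When discontinuation or a duration cap is
#' modelled, each year's `eligible(y) * share[y]` opens a start cohort, and a
#' cohort started in year s contributes `(1 - d)^(y - s)` person-years per
#' starter while `y - s < max_duration_years`.
#'
#' @inheritParams eligible_population
#' @return Person-years on treatment in each requested year.
#' @examples
#' spec <- bia_spec("A", prevalent_pool = 1000,
#'                  market_share = c(0.1, 0.2, 0.2, 0.2, 0.2),
#'                  units_per_day = 1, pack_size = 30, list_price = 100)
#' treated_person_years(spec, 1:2)
#' @export
treated_person_years <- function(spec, year) {
  validate_bia_spec(spec)
  check_year(spec, year)
  treated_person_years_(spec)[year]
}

treated_person_years_ <- function(spec) {
  f <- spec$features
  share <- spec$market_share * extra_product(spec, "market_share")
  elig <- eligible_population_(spec)
  if (!f[["discontinuation"]] && !f[["duration_of_treatment"]]) {
    return(elig * share)
  }
  # cohort bookkeeping: starters persist with geometric attrition up to the
  # duration cap
  starters <- elig * share
  h <- spec$horizon_years
  retain <- 1 - spec$discontinuation_rate
  dur <- spec$max_duration_years
  out <- numeric(h)
  for (y in seq_len(h)) {
    s <- seq_len(y)
    k <- y - s
    active <- k < dur
    out[y] <- sum(starters[s[active]] * retain^k[active])
  }
  out
}

#' Packs required per patient per year
#'
#' Converts the dosage parameters into annual pack demand for one patient:
#' `units_per_day * days_per_year / pack_size * adherence`, times any extra
#' dosage factors. Fractional packs are kept by default (population-level
#' expectation); `pack_rounding = "ceil_per_patient"` rounds the raw
#' packs-per-year up before applying adherence.
#'
#' @param spec A [bia_spec()].
#' @return Packs per patient-year (scalar).
#' @examples
#' spec <- bia_spec("A", prevalent_pool = 1, market_share = 1,
#'                  units_per_day = 2, pack_size = 28, list_price = 100)
#' packs_per_patient_year(spec)  # 2 * 365.25 / 28
#' @export
packs_per_patient_year <- function(spec) {
  validate_bia_spec(spec)
  packs_per_patient_year_(spec)
}

packs_per_patient_year_ <- function(spec) {
  base <- spec$units_per_day * spec$days_per_year / spec$pack_size
  if (spec$pack_rounding == "ceil_per_patient") base <- ceiling(base)
  base * spec$adherence * extra_product(spec, "dosage")
}

#' Gross drug budget impact over the model horizon
#'
#' The gross drug budget impact contains only the new drug's acquisition
#' costs: for each model year, treated person-years times packs per
#' patient-year times the list price (times any extra acquisition-cost
#' factors). Cost offsets from displaced drugs, rebates, fees and VAT are out
#' of scope.
#'
#' @param spec A [bia_spec()].
#' @return A `bia_gross` object with fields `drug_id`, `per_year_cost`,
#'   `per_year_treated`, `per_year_packs`; `as_tibble()` gives a per-year
#'   table.
#' @examples
#' spec <- bia_spec("A", prevalent_pool = 1000, market_share = 0.1,
#'                  units_per_day = 1, pack_size = 365.25 / 12,
#'                  list_price = 100)
#' gross_budget_impact(spec)
#' @export
gross_budget_impact <- function(spec) {
  validate_bia_spec(spec)
  treated <- treated_person_years_(spec)
  packs <- treated * packs_per_patient_year_(spec)
  cost <- packs * spec$list_price * extra_product(spec, "acquisition_cost")
  structure(
    list(
      drug_id = spec$drug_id,
      per_year_cost = cost,
      per_year_treated = treated,
      per_year_packs = packs
    ),
    class = "bia_gross"
  )
}

# Fast path used by the PSA loop: annual costs only, no validation and no
# result object.
gross_cost_ <- function(spec) {
  treated_person_years_(spec) * packs_per_patient_year_(spec) *
    spec$list_price * extra_product(spec, "acquisition_cost")
}

#' @export
print.bia_gross <- function(x, ...) {
  cat(sprintf("<bia_gross> drug %s\n", x$drug_id))
  print(as_tibble(x))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.bia_gross <- function(x, ...) {
  tibble(
    drug_id = x$drug_id,
    year = seq_along(x$per_year_cost),
    treated = x$per_year_treated,
    packs = x$per_year_packs,
    cost = x$per_year_cost
  )
}
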
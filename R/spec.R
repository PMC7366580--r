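# Model specification container: one drug/indication's gross budget-impact
# model, expressed in the four parameter categories used by national HTA
# agencies (population, market share, dosage, acquisition cost).

bia_feature_names <- c(
  "incidence", "prevalence", "population_growth",
  "adherence", "discontinuation", "duration_of_treatment"
)

bia_param_categories <- c(
  "population", "market_share", "dosage", "acquisition_cost"
)

bia_spec_fields <- c(
  "schema_version", "drug_id", "horizon_years", "features",
  "prevalent_pool", "incident_inflow", "growth_rate", "market_share",
  "adherence", "discontinuation_rate", "max_duration_years",
  "units_per_day", "pack_size", "list_price", "extra_parameters",
  "pack_rounding", "days_per_year"
)

#' Modelling feature flags for a budget-impact model
#'
#' The six structural modelling features commonly audited in budget-impact
#' submissions: whether the eligible population is built from incidence and/or
#' prevalence, whether it grows over the horizon, and whether adherence,
#' treatment discontinuation, or a maximum duration of treatment are modelled.
#'
#' @param incidence,prevalence Does the eligible population include an annual
#'   incident inflow and/or a prevalent pool? At least one must be `TRUE`.
#' @param population_growth Is the eligible population compounded by an annual
#'   growth rate?
#' @param adherence Is a (0, 1] adherence fraction applied to drug consumption?
#' @param discontinuation Do patients discontinue treatment at an annual rate?
#' @param duration_of_treatment Is treatment capped at a maximum number of
#'   years?
#' @return Named logical vector of length 6.
#' @examples
#' bia_features(prevalence = TRUE, population_growth = TRUE)
#' @export
bia_features <- function(incidence = FALSE, prevalence = TRUE,
                         population_growth = FALSE, adherence = FALSE,
                         discontinuation = FALSE,
                         duration_of_treatment = FALSE) {
  out <- c(
    incidence = incidence, prevalence = prevalence,
    population_growth = population_growth, adherence = adherence,
    discontinuation = discontinuation,
    duration_of_treatment = duration_of_treatment
  )
  if (!is.logical(out) || anyNA(out)) {
    abort("feature flags must be TRUE/FALSE")
  }
  out
}

normalise_extra_parameters <- function(extra) {
  if (is.null(extra) || (is.data.frame(extra) && nrow(extra) == 0L)) {
    return(data.frame(
      name = character(), category = character(),
      value = numeric(), psa_vary = logical(),
      stringsAsFactors = FALSE
    ))
  }
  extra <- as.data.frame(extra, stringsAsFactors = FALSE)
  if (is.null(extra$psa_vary)) extra$psa_vary <- TRUE
  need <- c("name", "category", "value", "psa_vary")
  if (!all(need %in% names(extra))) {
    abort("extra_parameters needs columns name, category, value, psa_vary")
  }
  extra[, need]
}

#' Construct a gross budget-impact model specification
#'
#' A `bia_spec` captures everything needed to compute a gross drug budget
#' impact — acquisition cost of the new drug alone — over a multi-year
#' horizon: eligible population, yearly market share, dosage-derived pack
#' demand, and the list price. Parameters are organised so that each field
#' maps to exactly one parameter record in one of the four audit categories
#' (see [spec_parameters()]), making parameter censuses well defined.
#'
#' Disabled features must carry their neutral value (growth rate 0, adherence
#' 1, discontinuation 0, unbounded duration, and a zero prevalent pool or
#' incident inflow); this is enforced at construction.
#'
#' @param drug_id Opaque drug/indication identifier.
#' @param horizon_years Positive integer horizon (model years 1..h, default 5).
#' @param features Named logical vector from [bia_features()].
#' @param prevalent_pool Prevalent eligible patients at baseline (persons).
#' @param incident_inflow Incident eligible patients per year (persons/year).
#' @param growth_rate Annual eligible-population growth rate (>= -1).
#' @param market_share Fraction of the eligible population receiving the drug
#'   in each year: scalar (recycled) or length-`horizon_years` vector in
#'   \[0, 1\]. Interpreted as point-in-year penetration, not cumulative uptake.
#' @param adherence Fraction of prescribed consumption actually dispensed,
#'   in (0, 1].
#' @param discontinuation_rate Annual probability of stopping treatment,
#'   in \[0, 1).
#' @param max_duration_years Maximum years on treatment (positive integer or
#'   `Inf` for unbounded).
#' @param units_per_day Dose units consumed per patient per day (> 0).
#' @param pack_size Units per pack or vial (> 0).
#' @param list_price Publicly available price per pack (currency, > 0). Held
#'   fixed in probabilistic sensitivity analysis.
#' @param extra_parameters Optional data frame (`name`, `category`, `value`,
#'   `psa_vary`) of additional multiplicative parameters: population and
#'   market-share entries are attrition fractions in \[0, 1\] multiplied into
#'   the eligible population / effective share; dosage and acquisition-cost
#'   entries are positive factors multiplied into packs per patient-year and
#'   annual cost respectively. These let a spec carry the parameter-count
#'   profile of a real applicant model.
#' @param pack_rounding `"none"` keeps fractional packs (population-level
#'   expectation); `"ceil_per_patient"` rounds packs per patient-year up.
#' @param days_per_year Days per model year (default 365.25).
#' @return An object of class `bia_spec`.
#' @examples
#' spec <- bia_spec("A", prevalent_pool = 1000, market_share = 0.1,
#'                  units_per_day = 1, pack_size = 30, list_price = 250)
#' spec
#' @seealso [gross_budget_impact()], [spec_parameters()], [write_spec()]
#' @export
bia_spec <- function(drug_id, horizon_years = 5L, features = bia_features(),
                     prevalent_pool = 0, incident_inflow = 0, growth_rate = 0,
                     market_share, adherence = 1, discontinuation_rate = 0,
                     max_duration_years = Inf, units_per_day, pack_size,
                     list_price, extra_parameters = NULL,
                     pack_rounding = c("none", "ceil_per_patient"),
                     days_per_year = 365.25) {
  pack_rounding <- match.arg(pack_rounding)
  horizon_years <- as.integer(horizon_years)
  if (length(market_share) == 1L) {
    market_share <- rep(market_share, horizon_years)
  }
  spec <- structure(
    list(
      schema_version = "1.0",
      drug_id = as.character(drug_id),
      horizon_years = horizon_years,
      features = features[bia_feature_names],
      prevalent_pool = as.numeric(prevalent_pool),
      incident_inflow = as.numeric(incident_inflow),
      growth_rate = as.numeric(growth_rate),
      market_share = as.numeric(market_share),
      adherence = as.numeric(adherence),
      discontinuation_rate = as.numeric(discontinuation_rate),
      max_duration_years = as.numeric(max_duration_years),
      units_per_day = as.numeric(units_per_day),
      pack_size = as.numeric(pack_size),
      list_price = as.numeric(list_price),
      extra_parameters = normalise_extra_parameters(extra_parameters),
      pack_rounding = pack_rounding,
      days_per_year = as.numeric(days_per_year)
    ),
    class = "bia_spec"
  )
  validate_bia_spec(spec)
  spec
}

#' Validate a budget-impact model specification
#'
#' Checks all structural invariants of a [bia_spec()]: positive horizon, a
#' source population (incidence and/or prevalence), fractions inside their
#' legal intervals, positive dosage and price, and neutral values for any
#' disabled feature. Called by the constructor; exposed for specs assembled
#' or deserialised by other means.
#'
#' @param spec A `bia_spec`.
#' @return `spec`, invisibly; errors on the first violated invariant.
#' @export
validate_bia_spec <- function(spec) {
  f <- spec$features
  chk <- function(ok, msg) if (!isTRUE(ok)) abort(paste0("invalid spec: ", msg))
  chk(is.character(spec$drug_id) && nzchar(spec$drug_id), "drug_id required")
  chk(is_scalar_number(spec$horizon_years) && spec$horizon_years >= 1,
      "horizon_years must be a positive integer")
  chk(is.logical(f) && length(f) == 6L && !anyNA(f) &&
        identical(names(f), bia_feature_names),
      "features must be the six named flags")
  chk(f[["incidence"]] || f[["prevalence"]],
      "a model must have a source population (incidence and/or prevalence)")
  chk(spec$prevalent_pool >= 0 && spec$incident_inflow >= 0,
      "population sizes must be nonnegative")
  if (!f[["prevalence"]]) chk(spec$prevalent_pool == 0,
      "prevalent_pool must be 0 when the prevalence feature is off")
  if (!f[["incidence"]]) chk(spec$incident_inflow == 0,
      "incident_inflow must be 0 when the incidence feature is off")
  chk(spec$growth_rate >= -1, "growth_rate must be >= -1")
  if (!f[["population_growth"]]) chk(spec$growth_rate == 0,
      "growth_rate must be 0 when the population_growth feature is off")
  chk(length(spec$market_share) == spec$horizon_years,
      "market_share must have one entry per horizon year")
  chk(all(spec$market_share >= 0 & spec$market_share <= 1),
      "market_share entries must lie in [0, 1]")
  chk(spec$adherence > 0 && spec$adherence <= 1,
      "adherence must lie in (0, 1]")
  if (!f[["adherence"]]) chk(spec$adherence == 1,
      "adherence must be 1 when the adherence feature is off")
  chk(spec$discontinuation_rate >= 0 && spec$discontinuation_rate < 1,
      "discontinuation_rate must lie in [0, 1)")
  if (!f[["discontinuation"]]) chk(spec$discontinuation_rate == 0,
      "discontinuation_rate must be 0 when the discontinuation feature is off")
  chk(spec$max_duration_years >= 1,
      "max_duration_years must be a positive number of years (or Inf)")
  if (!f[["duration_of_treatment"]]) chk(is.infinite(spec$max_duration_years),
      "max_duration_years must be unbounded when the duration feature is off")
  chk(spec$units_per_day > 0, "units_per_day must be positive")
  chk(spec$pack_size > 0, "pack_size must be positive")
  chk(spec$list_price > 0, "list_price must be positive")
  chk(spec$days_per_year > 0, "days_per_year must be positive")
  ex <- spec$extra_parameters
  chk(all(ex$category %in% bia_param_categories),
      "extra parameter categories must be one of population/market_share/dosage/acquisition_cost")
  chk(all(ex$value >= 0), "extra parameter values must be nonnegative")
  frac <- ex$category %in% c("population", "market_share")
  chk(all(ex$value[frac] <= 1),
      "population and market-share extra parameters are fractions in [0, 1]")
  invisible(spec)
}

#' @export
print.bia_spec <- function(x, ...) {
  on <- names(x$features)[x$features]
  counts <- table(factor(spec_parameters(x)$category,
                         levels = bia_param_categories))
  cat(sprintf("<bia_spec> drug %s, %d-year horizon\n", x$drug_id,
              x$horizon_years))
  cat("  features:", paste(on, collapse = ", "), "\n")
  cat(sprintf(
    "  parameters: %d population, %d market share, %d dosage, %d acquisition cost\n",
    counts[1], counts[2], counts[3], counts[4]
  ))
  cat(sprintf("  list price: %.2f per pack of %g units\n", x$list_price,
              x$pack_size))
  invisible(x)
}

#' Enumerate the parameter records of a model specification
#'
#' Flattens a [bia_spec()] into one row per parameter, each assigned to one of
#' the four audit categories. Yearly market shares count as one parameter per
#' horizon year (the convention behind "one for each of the 5 years" in
#' applicant submissions); the discontinuation rate is censused under market
#' share and adherence under dosage. The maximum treatment duration is a
#' structural cap, not a parameter record. The list price is the only record
#' with `psa_vary = FALSE`.
#'
#' @param spec A `bia_spec`.
#' @return Tibble with columns `name`, `category`, `value`, `psa_vary`, `role`.
#' @examples
#' spec <- bia_spec("A", prevalent_pool = 1000, market_share = 0.1,
#'                  units_per_day = 1, pack_size = 30, list_price = 250)
#' spec_parameters(spec)
#' @export
spec_parameters <- function(spec) {
  validate_bia_spec(spec)
  f <- spec$features
  rows <- list()
  add <- function(name, category, value, psa_vary = TRUE, role = "structural") {
    rows[[length(rows) + 1L]] <<- tibble(
      name = name, category = category, value = value,
      psa_vary = psa_vary, role = role
    )
  }
  if (f[["prevalence"]]) add("prevalent_pool", "population", spec$prevalent_pool)
  if (f[["incidence"]]) add("incident_inflow", "population", spec$incident_inflow)
  if (f[["population_growth"]]) add("growth_rate", "population", spec$growth_rate)
  add(sprintf("market_share_y%d", seq_len(spec$horizon_years)), "market_share",
      spec$market_share)
  if (f[["discontinuation"]]) {
    add("discontinuation_rate", "market_share", spec$discontinuation_rate)
  }
  add("units_per_day", "dosage", spec$units_per_day)
  add("pack_size", "dosage", spec$pack_size)
  if (f[["adherence"]]) add("adherence", "dosage", spec$adherence)
  add("list_price", "acquisition_cost", spec$list_price, psa_vary = FALSE,
      role = "list_price")
  ex <- spec$extra_parameters
  if (nrow(ex)) {
    add(ex$name, ex$category, ex$value, psa_vary = ex$psa_vary, role = "extra")
  }
  out <- bind_rows(rows)
  out$category <- factor(out$category, levels = bia_param_categories)
  out
}

#' Write a model specification to JSON
#'
#' One file per drug/indication, schema-versioned. `Inf` (unbounded treatment
#' duration) is stored as the string `"unbounded"`.
#'
#' @param spec A `bia_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_spec()]
#' @export
write_spec <- function(spec, path) {
  validate_bia_spec(spec)
  x <- unclass(spec)
  x$features <- as.list(spec$features)
  if (is.infinite(x$max_duration_years)) x$max_duration_years <- "unbounded"
  x$extra_parameters <- if (nrow(spec$extra_parameters)) {
    spec$extra_parameters
  } else {
    NULL
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(path)
}

#' Read a model specification from JSON
#'
#' Strict reader for files produced by [write_spec()]: unknown keys are
#' rejected rather than ignored, and the result is revalidated.
#'
#' @param path JSON file path.
#' @return A `bia_spec`.
#' @export
read_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(x), bia_spec_fields)
  if (length(unknown)) {
    abort(sprintf("unknown spec keys: %s", paste(unknown, collapse = ", ")))
  }
  if (!identical(x$schema_version, "1.0")) {
    abort("unsupported spec schema_version")
  }
  dur <- x$max_duration_years
  if (identical(dur, "unbounded") || is.null(dur)) dur <- Inf
  bia_spec(
    drug_id = x$drug_id,
    horizon_years = x$horizon_years,
    features = bia_features(
      incidence = x$features$incidence,
      prevalence = x$features$prevalence,
      population_growth = x$features$population_growth,
      adherence = x$features$adherence,
      discontinuation = x$features$discontinuation,
      duration_of_treatment = x$features$duration_of_treatment
    ),
    prevalent_pool = x$prevalent_pool,
    incident_inflow = x$incident_inflow,
    growth_rate = x$growth_rate,
    market_share = x$market_share,
    adherence = x$adherence,
    discontinuation_rate = x$discontinuation_rate,
    max_duration_years = dur,
    units_per_day = x$units_per_day,
    pack_size = x$pack_size,
    list_price = x$list_price,
    extra_parameters = x$extra_parameters,
    pack_rounding = x$pack_rounding %||% "none",
    days_per_year = x$days_per_year %||% 365.25
  )
}
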
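# HTA selection rules and the parameter-category / modelling-feature
# censuses over a set of model specifications.

bia_exclusion_reasons <- c(
  "no_bim", "multiple_indications", "not_reimbursed_full_year",
  "hospital_only", "hepatitis_c"
)

#' Read an HTA registry table
#'
#' CSV with one row per HTA and the five exclusion attributes:
#' `hta_id`, `has_budget_impact_model`, `n_indications`, `reimbursed`,
#' `months_reimbursed`, `hospital_only`, `hepatitis_c_indication`.
#'
#' @param path CSV file path.
#' @return Tibble of HTA records.
#' @export
read_registry <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("hta_id", "has_budget_impact_model", "n_indications",
            "reimbursed", "months_reimbursed", "hospital_only",
            "hepatitis_c_indication")
  if (!all(need %in% names(raw))) {
    abort(sprintf("registry CSV must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  out <- as_tibble(raw[, need])
  for (col in c("has_budget_impact_model", "reimbursed", "hospital_only",
                "hepatitis_c_indication")) {
    out[[col]] <- as.logical(out[[col]])
  }
  validate_registry(out)
  out
}

validate_registry <- function(registry) {
  if (any(!registry$reimbursed & registry$months_reimbursed != 0)) {
    abort("months_reimbursed must be 0 when reimbursed is FALSE")
  }
  if (any(registry$n_indications < 1)) {
    abort("n_indications must be a positive integer")
  }
  invisible(registry)
}

#' Apply the HTA exclusion rules to a registry
#'
#' Records are excluded, each under its first matching rule in the fixed
#' order: no budget-impact model available; multiple indications (claims data
#' cannot attribute utilisation to an indication); not reimbursed for at
#' least one full year (12 months); hospital-only drug; hepatitis C
#' indication (both invisible to the community claims database). Survivors
#' are included. The included set does not depend on the rule order — the
#' rules are properties of the record — but the per-reason tally does, so
#' the order is pinned.
#'
#' @param registry Tibble of HTA records (see [read_registry()]).
#' @return A `bia_exclusions` list: `included` (tibble of surviving
#'   records), `tally` (tibble `reason`, `n`), `n_included`, `n_total`.
#' @examples
#' reg <- generate_registry(113, c(21, 37, 28, 10, 5))
#' apply_exclusions(reg)
#' @export
apply_exclusions <- function(registry) {
  if (nrow(registry) == 0L) abort("registry is empty")
  validate_registry(registry)
  reason <- case_when(
    !registry$has_budget_impact_model ~ "no_bim",
    registry$n_indications > 1 ~ "multiple_indications",
    !registry$reimbursed | registry$months_reimbursed < 12 ~
      "not_reimbursed_full_year",
    registry$hospital_only ~ "hospital_only",
    registry$hepatitis_c_indication ~ "hepatitis_c",
    TRUE ~ NA_character_
  )
  per_reason <- map_int(bia_exclusion_reasons,
                        function(r) sum(reason == r, na.rm = TRUE))
  tally <- tibble(reason = bia_exclusion_reasons, n = per_reason)
  included <- registry[is.na(reason), ]
  structure(
    list(
      included = included,
      tally = tally,
      n_included = nrow(included),
      n_total = nrow(registry)
    ),
    class = "bia_exclusions"
  )
}

#' @export
print.bia_exclusions <- function(x, ...) {
  cat(sprintf("<bia_exclusions> %d HTAs considered\n", x$n_total))
  for (i in seq_len(nrow(x$tally))) {
    cat(sprintf("  excluded, %s: %d\n", x$tally$reason[i], x$tally$n[i]))
  }
  cat(sprintf("  included: %d\n", x$n_included))
  invisible(x)
}

#' Parameter-category census over model specifications
#'
#' Counts each drug's parameter records per audit category (see
#' [spec_parameters()]), alongside its feature flags.
#'
#' @param specs List of [bia_spec()] objects.
#' @return Tibble with one row per drug: `drug_id`, `n_population`,
#'   `n_market_share`, `n_dosage`, `n_acquisition_cost`, and the six feature
#'   flag columns.
#' @export
parameter_census <- function(specs) {
  if (!length(specs)) abort("no specs supplied")
  bind_rows(map(specs, function(s) {
    counts <- table(spec_parameters(s)$category)
    flags <- as.list(s$features)
    tibble(
      drug_id = s$drug_id,
      n_population = as.integer(counts[["population"]]),
      n_market_share = as.integer(counts[["market_share"]]),
      n_dosage = as.integer(counts[["dosage"]]),
      n_acquisition_cost = as.integer(counts[["acquisition_cost"]]),
      !!!flags
    )
  }))
}

#' Summary ranges for a parameter-category census
#'
#' @param census Tibble with columns `n_population`, `n_market_share`,
#'   `n_dosage`, `n_acquisition_cost` — from [parameter_census()] or a
#'   transcribed audit table such as [ncpe_parameter_counts()].
#' @return Tibble with one row per category: `category`, `min`, `max`,
#'   `mode` (most common count, ties towards the smaller).
#' @export
census_ranges <- function(census) {
  cols <- paste0("n_", bia_param_categories)
  if (!all(cols %in% names(census))) {
    abort(sprintf("census must have columns: %s", paste(cols, collapse = ", ")))
  }
  bind_rows(map(bia_param_categories, function(cat) {
    x <- census[[paste0("n_", cat)]]
    tibble(category = cat, min = min(x), max = max(x), mode = stat_mode(x))
  }))
}

#' Modelling-feature census
#'
#' Counts how many models include each of the six structural modelling
#' features.
#'
#' @param x List of [bia_spec()] objects, or a data frame with logical
#'   columns named after the features (e.g. [ncpe_model_features()]).
#' @return Tibble `feature`, `n`.
#' @export
feature_census <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) == 0L) abort("no models supplied")
    flags <- x[, intersect(bia_feature_names, names(x)), drop = FALSE]
  } else {
    if (!length(x)) abort("no specs supplied")
    flags <- as.data.frame(do.call(rbind, map(x, function(s) s$features)))
  }
  tibble(
    feature = names(flags),
    n = unname(map_int(flags, function(col) sum(as.logical(col))))
  )
}
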
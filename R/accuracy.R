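# Predicted vs realised comparison: signed yearly prediction-error
# percentages, per-drug over/under classification, summary extremes, and
# PSA-coverage summaries.

#' Signed prediction-error percentage
#'
#' `(realised - predicted) / predicted * 100`: positive values are model
#' underpredictions (realised utilisation exceeded the forecast), negative
#' values overpredictions. The error is bounded below by -100% (realised of
#' zero) but unbounded above. A literal "predicted as a percentage of
#' realised" variant is available for sensitivity checks via
#' `formula = "share_of_realised"`, which returns
#' `predicted / realised * 100`.
#'
#' @param predicted Predicted annual gross budget impact (> 0); vectorised.
#' @param realised Realised annual utilisation at list price (>= 0).
#' @param formula `"signed_error"` (default) or `"share_of_realised"`.
#' @return Signed percentages (default formula), `NA` where either input is
#'   `NA`.
#' @examples
#' prediction_error_pct(100, 100)   # 0
#' prediction_error_pct(200, 100)   # -50: overprediction
#' prediction_error_pct(100, 1117)  # +1017: underprediction
#' @export
prediction_error_pct <- function(predicted, realised,
                                 formula = c("signed_error",
                                             "share_of_realised")) {
  formula <- match.arg(formula)
  if (any(predicted <= 0, na.rm = TRUE)) {
    abort("prediction error is undefined for predicted <= 0")
  }
  if (any(realised < 0, na.rm = TRUE)) {
    abort("realised utilisation must be nonnegative")
  }
  switch(formula,
    signed_error = (realised - predicted) / predicted * 100,
    share_of_realised = predicted / realised * 100
  )
}

#' Classify a drug's yearly prediction errors
#'
#' All unmasked years negative: `overpredicted_all_years`; all positive:
#' `underpredicted_all_years`; otherwise `mixed`. The majority
#' classification assigns the sign carried by a strict majority of unmasked
#' years (`tied` when split evenly, with zeros counting to neither side).
#'
#' @param errors Numeric vector of yearly signed error percentages, `NA` for
#'   years without a full realised window.
#' @return One-row tibble: `classification`, `majority_classification`,
#'   `n_years`.
#' @examples
#' classify_drug(c(-36, -57, NA, NA, NA))  # overpredicted_all_years
#' classify_drug(c(420, 22, -21))          # mixed, majority under
#' @export
classify_drug <- function(errors) {
  e <- errors[!is.na(errors)]
  if (!length(e)) abort("insufficient data: no unmasked years")
  classification <- if (all(e < 0)) {
    "overpredicted_all_years"
  } else if (all(e > 0)) {
    "underpredicted_all_years"
  } else {
    "mixed"
  }
  n_under <- sum(e > 0)
  n_over <- sum(e < 0)
  majority <- if (n_under > n_over) {
    "under"
  } else if (n_over > n_under) {
    "over"
  } else {
    "tied"
  }
  tibble(classification = classification,
         majority_classification = majority,
         n_years = length(e))
}

#' Per-drug accuracy table from yearly prediction errors
#'
#' @param errors Long tibble with columns `drug_id`, `year`, `error_pct`
#'   (`NA` where no full realised year exists).
#' @return Tibble with one row per drug: classification columns from
#'   [classify_drug()] plus `n_years` of comparison.
#' @export
accuracy_table <- function(errors) {
  errors |>
    group_by(.data$drug_id) |>
    summarise(classify_drug(.data$error_pct), .groups = "drop")
}

#' Extreme prediction errors across all drugs and years
#'
#' @param errors Numeric vector, or a tibble with an `error_pct` column.
#' @return Named numeric `c(most_negative, most_positive)`.
#' @examples
#' summarize_extremes(c(-94, 10, 1017))
#' @export
summarize_extremes <- function(errors) {
  if (is.data.frame(errors)) errors <- errors$error_pct
  e <- errors[!is.na(errors)]
  if (!length(e)) abort("insufficient data: no unmasked errors")
  c(most_negative = min(e), most_positive = max(e))
}

#' Count drugs whose PSA bounds captured every available year
#'
#' A drug counts as consistently captured when every year with a realised
#' value (status not `not_available`) is `inside_psa_bounds`.
#'
#' @param coverage Tibble with columns `drug_id`, `year`, `status` — e.g.
#'   rows from [classify_coverage()] bound together, or [ncpe_psa_coverage()].
#' @return Integer count of consistently-captured drugs.
#' @export
coverage_summary <- function(coverage) {
  if (nrow(coverage) == 0L) abort("coverage table is empty")
  per_drug <- coverage |>
    filter(.data$status != "not_available") |>
    group_by(.data$drug_id) |>
    summarise(all_inside = all(.data$status == "inside_psa_bounds"),
              .groups = "drop")
  sum(per_drug$all_inside)
}
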
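# Monthly dispensing ledger (claims-database style) and its aggregation to
# annual realised utilisation at list price, anchored at the month of
# reimbursement.

#' Read a monthly dispensing ledger
#'
#' Parses a CSV with columns `drug_id`, `month` (`YYYY-MM`), `quantity_packs`
#' and `expenditure_list_price`, validates every row, and sums duplicate
#' drug-months. Expenditure is taken to be valued at the publicly available
#' list price (no rebates, pharmacist fees or VAT).
#'
#' @param path CSV file path.
#' @return A `bia_dispensing` tibble, one row per drug-month, sorted.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("drug_id,month,quantity_packs,expenditure_list_price",
#'              "A,2013-01,10,1000", "A,2013-01,5,500"), path)
#' read_dispensing(path)  # duplicate month summed
#' @export
read_dispensing <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("drug_id", "month", "quantity_packs", "expenditure_list_price")
  if (!all(need %in% names(raw))) {
    abort(sprintf("dispensing CSV must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  if (nrow(raw) == 0L) {
    return(structure(
      tibble(drug_id = character(), month = character(),
             quantity_packs = numeric(), expenditure_list_price = numeric()),
      class = c("bia_dispensing", class(tibble()))
    ))
  }
  bad_month <- !grepl("^\\d{4}-(0[1-9]|1[0-2])$", raw$month)
  if (any(bad_month)) {
    abort(sprintf("malformed month at row(s): %s",
                  paste(which(bad_month), collapse = ", ")))
  }
  qty <- suppressWarnings(as.numeric(raw$quantity_packs))
  exp <- suppressWarnings(as.numeric(raw$expenditure_list_price))
  bad <- is.na(qty) | is.na(exp) | qty < 0 | exp < 0
  if (any(bad)) {
    abort(sprintf("negative or non-numeric quantity/expenditure at row(s): %s",
                  paste(which(bad), collapse = ", ")))
  }
  out <- tibble(
    drug_id = raw$drug_id, month = raw$month,
    quantity_packs = qty, expenditure_list_price = exp
  ) |>
    group_by(.data$drug_id, .data$month) |>
    summarise(
      quantity_packs = sum(.data$quantity_packs),
      expenditure_list_price = sum(.data$expenditure_list_price),
      .groups = "drop"
    ) |>
    arrange(.data$drug_id, .data$month)
  structure(out, class = c("bia_dispensing", class(out)))
}

#' Aggregate dispensing records into annual realised utilisation
#'
#' Sums list-price expenditure over consecutive 12-month windows anchored at
#' the month of reimbursement (the first month with nonzero dispensing unless
#' a start is declared): window y covers months `12(y-1)+1 .. 12y` after the
#' anchor. Windows extending past `analysis_end_month` are masked as not
#' full; months with no record inside a window contribute zero. At most
#' `horizon` windows are produced. `year_mode = "calendar"` instead uses
#' calendar years (January–December), in which case the launch year is only
#' full when reimbursement starts in January.
#'
#' @param records A `bia_dispensing` tibble from [read_dispensing()] (or any
#'   tibble with the same columns).
#' @param drug_id Drug to aggregate. Unknown drugs yield an empty series with
#'   a warning, not an error.
#' @param start_month Declared reimbursement month (`"YYYY-MM"`), or `NULL`
#'   to use the first month with nonzero dispensing.
#' @param horizon Maximum number of yearly windows (default 5).
#' @param analysis_end_month Last month covered by the analysis
#'   (`"YYYY-MM"`); defaults to the last month present in `records` (any
#'   drug).
#' @param year_mode `"anchored"` (rolling 12-month windows, default) or
#'   `"calendar"`.
#' @return A `bia_realised` tibble: `drug_id`, `year`, `realised`, `full`;
#'   attribute `reimbursement_start` carries the anchor month.
#' @export
annual_realised <- function(records, drug_id, start_month = NULL,
                            horizon = 5L, analysis_end_month = NULL,
                            year_mode = c("anchored", "calendar")) {
  year_mode <- match.arg(year_mode)
  rec <- records[records$drug_id == drug_id, ]
  empty <- structure(
    tibble(drug_id = character(), year = integer(), realised = numeric(),
           full = logical()),
    class = c("bia_realised", class(tibble()))
  )
  if (nrow(rec) == 0L) {
    warning(sprintf("no dispensing records for drug '%s'", drug_id))
    return(empty)
  }
  idx <- month_to_index(rec$month)
  nonzero <- rec$quantity_packs > 0 | rec$expenditure_list_price > 0
  start_idx <- if (is.null(start_month)) {
    if (!any(nonzero)) {
      warning(sprintf("drug '%s' has no nonzero dispensing", drug_id))
      return(empty)
    }
    min(idx[nonzero])
  } else {
    month_to_index(start_month)
  }
  end_idx <- if (is.null(analysis_end_month)) {
    max(month_to_index(records$month))
  } else {
    month_to_index(analysis_end_month)
  }
  if (start_idx > end_idx) {
    abort("start_month must not be after analysis_end_month")
  }
  years <- seq_len(horizon)
  if (year_mode == "anchored") {
    w_start <- start_idx + 12L * (years - 1L)
    w_end <- w_start + 11L
  } else {
    y0 <- start_idx %/% 12L
    w_start <- (y0 + years - 1L) * 12L
    w_end <- w_start + 11L
  }
  realised <- map_dbl(years, function(y) {
    inside <- idx >= max(w_start[y], start_idx) & idx <= min(w_end[y], end_idx)
    if (w_start[y] > end_idx) NA_real_ else sum(rec$expenditure_list_price[inside])
  })
  full <- w_end <= end_idx & w_start >= start_idx
  out <- tibble(drug_id = drug_id, year = years, realised = realised,
                full = full & !is.na(realised))
  attr(out, "reimbursement_start") <- index_to_month(start_idx)
  structure(out, class = c("bia_realised", class(tibble())))
}
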
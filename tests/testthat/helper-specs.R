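# Shared fixture builders. Everything is generated in code; no data files.

toy_spec <- function(drug_id = "TOY", prevalent_pool = 1000,
                     market_share = 0.1, units_per_day = 1, pack_size = 30,
                     list_price = 100, ...) {
  bia_spec(
    drug_id = drug_id, prevalent_pool = prevalent_pool,
    market_share = market_share, units_per_day = units_per_day,
    pack_size = pack_size, list_price = list_price, ...
  )
}

# A 1-year, 5-varying-parameter multiplicative spec for corner enumeration.
corner_spec <- function(pool = 1000, share = 0.5, adherence = 0.8,
                        units = 1, pack = 30, price = 100) {
  bia_spec(
    drug_id = "CORNER", horizon_years = 1,
    features = bia_features(prevalence = TRUE, adherence = TRUE),
    prevalent_pool = pool, market_share = share, adherence = adherence,
    units_per_day = units, pack_size = pack, list_price = price
  )
}

# Year-1 cost of corner_spec with each varying parameter scaled by the signs
# in `dirs` (+1 / -1) times range r. Used as the independent corner oracle.
corner_cost <- function(dirs, r = 0.2) {
  f <- 1 + r * dirs
  s <- corner_spec(
    pool = 1000 * f[1], share = min(1, 0.5 * f[2]),
    adherence = min(1, 0.8 * f[3]), units = 1 * f[4], pack = 30 * f[5]
  )
  gross_budget_impact(s)$per_year_cost[1]
}

# Write a dispensing CSV and read it back.
dispensing_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c("drug_id,month,quantity_packs,expenditure_list_price", lines),
             path)
  path
}
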
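test_that("eligible population compounds growth and attrition factors", {
  s <- toy_spec(prevalent_pool = 1000)
  expect_equal(eligible_population(s, 1), 1000)

  s2 <- toy_spec(prevalent_pool = 1000,
                 features = bia_features(population_growth = TRUE),
                 growth_rate = 0.10)
  expect_equal(eligible_population(s2, 2), 1100)

  # hand-computed product: (800 + 100) * 1.05^2 * 0.5 * 0.8 = 396.90
  s3 <- bia_spec(
    "X", features = bia_features(incidence = TRUE, population_growth = TRUE),
    prevalent_pool = 800, incident_inflow = 100, growth_rate = 0.05,
    market_share = 0.1, units_per_day = 1, pack_size = 30, list_price = 100,
    extra_parameters = data.frame(name = c("f1", "f2"),
                                  category = "population",
                                  value = c(0.5, 0.8), psa_vary = TRUE)
  )
  expect_equal(eligible_population(s3, 3), 396.90)

  expect_error(eligible_population(s, 6), "year")
  expect_error(eligible_population(s, 0), "year")
})

test_that("treated person-years follow point-in-year shares and cohorts", {
  s <- toy_spec(prevalent_pool = 1000, market_share = c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(treated_person_years(s, 1), 100)
  expect_equal(treated_person_years(s, 3), 300)  # no cohort accumulation

  # one survival step: cohort of 100 starts year 1, half discontinue
  s2 <- toy_spec(prevalent_pool = 1000,
                 market_share = c(0.1, 0, 0, 0, 0),
                 features = bia_features(discontinuation = TRUE),
                 discontinuation_rate = 0.5)
  expect_equal(treated_person_years(s2, 2), 50)

  # cohort-table oracle: starters 100 (y1), 200 (y2); 20% discontinuation;
  # 2-year duration cap -> y1 cohort expired by year 3, y2 contributes 160
  s3 <- toy_spec(prevalent_pool = 1000,
                 market_share = c(0.1, 0.2, 0, 0, 0),
                 features = bia_features(discontinuation = TRUE,
                                         duration_of_treatment = TRUE),
                 discontinuation_rate = 0.2, max_duration_years = 2)
  expect_equal(treated_person_years(s3, 3), 200 * 0.8)
  expect_equal(treated_person_years(s3, 1), 100)
  expect_equal(treated_person_years(s3, 2), 200 + 100 * 0.8)
})

test_that("packs per patient-year convert dosage, pack size and adherence", {
  expect_equal(packs_per_patient_year(toy_spec(pack_size = 365.25)), 1)
  s <- toy_spec(units_per_day = 2, pack_size = 28)
  expect_equal(packs_per_patient_year(s), 2 * 365.25 / 28)
  s2 <- toy_spec(units_per_day = 2, pack_size = 28,
                 features = bia_features(adherence = TRUE), adherence = 0.8)
  expect_equal(packs_per_patient_year(s2), 2 * 365.25 / 28 * 0.8)
  # ceiling mode rounds packs up before adherence
  s3 <- toy_spec(units_per_day = 2, pack_size = 28,
                 pack_rounding = "ceil_per_patient")
  expect_equal(packs_per_patient_year(s3), ceiling(2 * 365.25 / 28))
})

test_that("gross budget impact is the product of its stages", {
  # 1000 patients, 10% share, 12 packs/patient-year, 100 per pack
  s <- toy_spec(prevalent_pool = 1000, market_share = 0.1,
                units_per_day = 1, pack_size = 365.25 / 12, list_price = 100)
  g <- gross_budget_impact(s)
  expect_equal(g$per_year_cost[1], 120000)
  expect_equal(g$per_year_cost, g$per_year_packs * 100)
  expect_equal(g$per_year_packs, g$per_year_treated * 12)

  expect_equal(gross_budget_impact(toy_spec(market_share = 0))$per_year_cost,
               rep(0, 5))

  s2 <- toy_spec(list_price = 200)
  expect_equal(gross_budget_impact(s2)$per_year_cost,
               2 * gross_budget_impact(toy_spec(list_price = 100))$per_year_cost)
})

test_that("costs are homogeneous in price and population scale", {
  prof <- spec_profile(seed = 401)
  for (i in 1:5) {
    s <- generate_spec(prof, index = i)
    base <- gross_budget_impact(s)$per_year_cost
    sp <- s; sp$list_price <- s$list_price * 3
    expect_equal(gross_budget_impact(sp)$per_year_cost, 3 * base)
    sk <- s
    sk$prevalent_pool <- s$prevalent_pool * 2
    sk$incident_inflow <- s$incident_inflow * 2
    expect_equal(gross_budget_impact(sk)$per_year_cost, 2 * base)
  }
})

test_that("with all optional features off the impact has a closed form", {
  s <- toy_spec(prevalent_pool = 750, market_share = seq(0.1, 0.5, 0.1),
                units_per_day = 3, pack_size = 28, list_price = 55)
  expected <- 750 * seq(0.1, 0.5, 0.1) * (3 * 365.25 / 28) * 55
  expect_equal(gross_budget_impact(s)$per_year_cost, expected)
})

test_that("costs are monotone in every parameter", {
  prof <- spec_profile(seed = 402)
  bump <- function(s, field, factor, cap = Inf) {
    s[[field]] <- pmin(cap, s[[field]] * factor)
    s
  }
  for (i in 1:5) {
    s <- generate_spec(prof, index = i)
    base <- gross_budget_impact(s)$per_year_cost
    up <- list(
      bump(s, "prevalent_pool", 1.1),
      bump(s, "incident_inflow", 1.1),
      bump(s, "market_share", 1.05, cap = 1),
      bump(s, "units_per_day", 1.1),
      bump(s, "list_price", 1.1)
    )
    for (su in up) {
      expect_true(all(gross_budget_impact(su)$per_year_cost >= base - 1e-9))
    }
    # more discontinuation can only lose person-years
    if (s$features[["discontinuation"]]) {
      sd <- s
      sd$discontinuation_rate <- min(0.99, s$discontinuation_rate * 1.5)
      expect_true(all(gross_budget_impact(sd)$per_year_cost <= base + 1e-9))
    }
  }
})

test_that("cohort bookkeeping never creates patients", {
  s <- toy_spec(prevalent_pool = 1000,
                market_share = c(0.1, 0.2, 0.3, 0.3, 0.3),
                features = bia_features(discontinuation = TRUE,
                                        duration_of_treatment = TRUE),
                discontinuation_rate = 0.15, max_duration_years = 3)
  treated <- treated_person_years(s, 1:5)
  starters <- eligible_population(s, 1:5) * s$market_share
  # in any year, people on treatment cannot exceed all who ever started
  expect_true(all(treated <= cumsum(starters) + 1e-9))
})
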
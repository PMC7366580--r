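test_that("spec generation is reproducible and respects the profile", {
  prof <- spec_profile(seed = 21)
  s1 <- generate_spec(prof, index = 4)
  s2 <- generate_spec(prof, index = 4)
  expect_equal(s1, s2)
  expect_false(identical(s1, generate_spec(prof, index = 5)))

  # parameter counts fall inside the profile ranges across many draws
  specs <- lapply(1:100, function(i) generate_spec(prof, index = i))
  cen <- parameter_census(specs)
  expect_true(all(cen$n_population >= 3 & cen$n_population <= 91))
  expect_true(all(cen$n_market_share >= 5 & cen$n_market_share <= 30))
  expect_true(all(cen$n_dosage >= 1 & cen$n_dosage <= 4))
  expect_true(all(cen$n_acquisition_cost >= 1 & cen$n_acquisition_cost <= 3))
  # year-1 eligible population stays in the documented realistic range
  elig <- vapply(specs, function(s) eligible_population(s, 1), numeric(1))
  expect_true(all(elig >= 100 & elig <= 100000))
  expect_true(all(vapply(specs, function(s) s$features[["prevalence"]] ||
                           s$features[["incidence"]], logical(1))))
})

test_that("degenerate feature marginals are honoured", {
  prof <- spec_profile(seed = 22, feature_probs = c(
    incidence = 0, prevalence = 1, population_growth = 0, adherence = 1,
    discontinuation = 0, duration_of_treatment = 0
  ))
  specs <- lapply(1:20, function(i) generate_spec(prof, index = i))
  expect_true(all(vapply(specs, function(s) s$features[["adherence"]],
                         logical(1))))
  expect_false(any(vapply(specs, function(s) s$features[["incidence"]],
                          logical(1))))
})

test_that("zero forecast error closes the loop exactly", {
  prof <- spec_profile(seed = 23)
  s <- generate_spec(prof, index = 2)
  led <- generate_dispensing(s, error_model(sigma = 0, bias = 1, seed = 1),
                             months_available = 60)
  rs <- annual_realised(led, s$drug_id)
  expect_true(all(rs$full))
  pred <- gross_budget_impact(s)$per_year_cost
  expect_equal(rs$realised, pred, tolerance = 1e-10)
  expect_equal(prediction_error_pct(pred, rs$realised), rep(0, 5),
               tolerance = 1e-8)
})

test_that("a pure bias shifts every year's error by (bias - 1) x 100", {
  prof <- spec_profile(seed = 24)
  s <- generate_spec(prof, index = 1)
  led <- generate_dispensing(s, error_model(sigma = 0, bias = 11.17, seed = 1),
                             months_available = 60)
  rs <- annual_realised(led, s$drug_id)
  pred <- gross_budget_impact(s)$per_year_cost
  expect_equal(prediction_error_pct(pred, rs$realised), rep(1017, 5),
               tolerance = 1e-8)
})

test_that("truncated ledgers mask partial years", {
  s <- generate_spec(spec_profile(seed = 25), index = 1)
  led <- generate_dispensing(s, error_model(sigma = 0, seed = 1),
                             months_available = 18)
  rs <- annual_realised(led, s$drug_id)
  expect_true(rs$full[1])
  expect_false(any(rs$full[2:5]))
})

test_that("monthly spread preserves annual totals under either ramp", {
  s <- generate_spec(spec_profile(seed = 26), index = 1)
  pred <- gross_budget_impact(s)$per_year_cost
  for (ramp in c("linear", "flat")) {
    led <- generate_dispensing(s, error_model(sigma = 0, seed = 1),
                               months_available = 60, ramp = ramp)
    yr1 <- led$expenditure_list_price[1:12]
    expect_equal(sum(yr1), pred[1], tolerance = 1e-10)
    if (ramp == "linear") expect_true(all(diff(yr1) > 0)) else {
      expect_equal(max(yr1) - min(yr1), 0, tolerance = 1e-10)
    }
    # pack quantities are expenditure at list price
    expect_equal(led$quantity_packs * s$list_price,
                 led$expenditure_list_price)
  }
})

test_that("registry generation matches requested exclusion mixes", {
  reg <- generate_registry(113, c(21, 37, 28, 10, 5))
  expect_equal(nrow(reg), 113)
  ex <- apply_exclusions(reg)
  expect_equal(ex$tally$n, c(21L, 37L, 28L, 10L, 5L))
  expect_equal(ex$n_included, 12L)

  expect_equal(apply_exclusions(generate_registry(10, rep(0, 5)))$n_included,
               10)
  expect_error(generate_registry(5, c(6, 0, 0, 0, 0)), "at most total")
})
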
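test_that("sampling respects the interval, the clamp, and degenerate ranges", {
  s <- toy_spec(prevalent_pool = 10)
  cfg0 <- psa_config(range_fraction = 0, seed = 3)
  expect_equal(sample_spec(s, cfg0, 1), s)

  cfg <- psa_config(range_fraction = 0.2, seed = 3)
  pools <- vapply(1:200, function(i) sample_spec(s, cfg, i)$prevalent_pool,
                  numeric(1))
  expect_true(all(pools >= 8 & pools <= 12))
  expect_gt(max(pools), 11)  # draws actually spread over the support
  expect_lt(min(pools), 9)

  s95 <- toy_spec(market_share = 0.95)
  shares <- vapply(1:200, function(i) {
    max(sample_spec(s95, cfg, i)$market_share)
  }, numeric(1))
  expect_true(all(shares <= 1))
  expect_true(any(shares == 1))  # clamp engaged

  # the agreed list price is never varied by default
  prices <- vapply(1:50, function(i) sample_spec(s, cfg, i)$list_price,
                   numeric(1))
  expect_true(all(prices == s$list_price))
})

test_that("alternative distributions stay on the same +/-20% support", {
  s <- toy_spec(prevalent_pool = 10)
  for (dist in c("triangular", "normal_truncated")) {
    cfg <- psa_config(range_fraction = 0.2, distribution = dist, seed = 5)
    pools <- vapply(1:200, function(i) sample_spec(s, cfg, i)$prevalent_pool,
                    numeric(1))
    expect_true(all(pools >= 8 & pools <= 12))
    # both pile mass near the point value relative to uniform
    expect_gt(mean(pools > 9 & pools < 11), 0.5)
  }
})

test_that("zero range collapses the PSA onto the deterministic cost", {
  s <- toy_spec()
  p <- run_psa(s, psa_config(n_simulations = 50, range_fraction = 0, seed = 1))
  expect_equal(p$per_year_min, p$deterministic)
  expect_equal(p$per_year_max, p$deterministic)
})

test_that("the same seed reproduces the PSA exactly", {
  s <- toy_spec()
  p1 <- run_psa(s, psa_config(n_simulations = 300, seed = 11))
  p2 <- run_psa(s, psa_config(n_simulations = 300, seed = 11))
  expect_identical(p1$per_year_draws, p2$per_year_draws)
  # and early draws are unchanged when the simulation count grows
  p3 <- run_psa(s, psa_config(n_simulations = 500, seed = 11))
  expect_identical(p3$per_year_draws[1:300, ], p1$per_year_draws)
})

test_that("simulated extremes stay inside the enumerated corner envelope", {
  # 5 varying multiplicative parameters -> 2^5 corner evaluations bracket
  # every possible draw of the monotone engine
  dirs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 5)))
  corner_costs <- apply(dirs, 1, corner_cost)
  p <- run_psa(corner_spec(), psa_config(n_simulations = 1000, seed = 7))
  expect_gte(p$per_year_min[1], min(corner_costs) - 1e-9)
  expect_lte(p$per_year_max[1], max(corner_costs) + 1e-9)
  # and the all-low / all-high corners are the envelope's own extremes
  expect_equal(min(corner_costs), corner_cost(c(-1, -1, -1, -1, 1)))
})

test_that("widening the range never narrows the simulated bounds", {
  s <- toy_spec()
  prev <- run_psa(s, psa_config(n_simulations = 1000, range_fraction = 0.05,
                                seed = 13))
  for (r in c(0.10, 0.20, 0.30)) {
    cur <- run_psa(s, psa_config(n_simulations = 1000, range_fraction = r,
                                 seed = 13))
    expect_true(all(cur$per_year_min <= prev$per_year_min + 1e-9))
    expect_true(all(cur$per_year_max >= prev$per_year_max - 1e-9))
    prev <- cur
  }
})

test_that("the deterministic point estimate lies inside the bounds", {
  prof <- spec_profile(seed = 403)
  for (i in 1:3) {
    s <- generate_spec(prof, index = i)
    p <- run_psa(s, psa_config(n_simulations = 1000, seed = 17))
    expect_true(all(p$per_year_min <= p$deterministic))
    expect_true(all(p$per_year_max >= p$deterministic))
  }
})

test_that("coverage classification is inclusive and masks missing years", {
  s <- toy_spec()
  p <- run_psa(s, psa_config(n_simulations = 500, seed = 19))
  realised <- tibble::tibble(
    drug_id = s$drug_id, year = 1:5, realised = p$per_year_mean,
    full = TRUE
  )
  expect_true(all(classify_coverage(p, realised)$status == "inside_psa_bounds"))

  realised$realised <- 0  # strictly below positive bounds
  expect_true(all(classify_coverage(p, realised)$status == "outside_psa_bounds"))

  # a single realised year on a 5-year PSA leaves four not_available entries
  one_year <- tibble::tibble(drug_id = s$drug_id, year = 1,
                             realised = p$per_year_mean[1], full = TRUE)
  st <- classify_coverage(p, one_year)$status
  expect_equal(st, c("inside_psa_bounds", rep("not_available", 4)))

  # exact boundary counts as inside (closed interval)
  at_min <- tibble::tibble(drug_id = s$drug_id, year = 1,
                           realised = p$per_year_min[1], full = TRUE)
  expect_equal(classify_coverage(p, at_min)$status[1], "inside_psa_bounds")

  other <- tibble::tibble(drug_id = "OTHER", year = 1, realised = 1,
                          full = TRUE)
  expect_error(classify_coverage(p, other), "mismatch")
})
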
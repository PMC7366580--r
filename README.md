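# biaval

Retrospective validation of drug budget-impact models against realised
utilisation.

## The problem

Before a health system reimburses a new drug, the applicant submits a budget
impact analysis (BIA): a forecast of the drug's financial consequence over a
finite horizon, typically five years. National HTA agencies use these
forecasts for affordability decisions, but whether they turn out to be
accurate can only be judged retrospectively, by comparing the prediction
with the expenditure actually reimbursed through the claims system. `biaval`
is for analysts performing such audits: it recreates applicant-style gross
budget-impact models, quantifies their parameter uncertainty, aggregates
claims-style dispensing ledgers, and scores predictions against reality.

## The model

The core is a canonical multiplicative cohort engine for the **gross drug
budget impact** — the new drug's acquisition cost only, at list price. For
model year *y* = 1..H:

- eligible(y) = (prevalent pool + incident inflow) × (1 + g)^(y−1) ×
  ∏ attrition fractions
- treated(y) = eligible(y) × m_y (point-in-year market share), with cohort
  bookkeeping — starters persist with (1 − d)^(y−s) attrition up to a
  duration cap — when discontinuation or duration of treatment is modelled
- cost C_y = treated(y) × (u × 365.25 / q) × a × π
  (daily dose u, pack size q, adherence a, list price π)

Around the engine:

- **PSA** (`run_psa()`): 1000 Monte-Carlo draws, every parameter except the
  agreed list price varied independently within ±20% (uniform by default),
  per-year min/max bounds, and coverage classification of realised spending
  against those bounds.
- **Realised utilisation** (`read_dispensing()`, `annual_realised()`):
  monthly list-price expenditure summed over 12-month windows anchored at
  the month of reimbursement; partial windows are masked.
- **Accuracy** (`prediction_error_pct()`, `accuracy_table()`): signed yearly
  errors (realised − predicted)/predicted × 100, positive = underprediction;
  drug-level over/under classification and extremes.
- **Selection & censuses** (`apply_exclusions()`, `parameter_census()`,
  `feature_census()`): the audit's five exclusion rules and the
  parameter-category / modelling-feature tallies.
- **Synthetic data** (`generate_spec()`, `generate_dispensing()`,
  `generate_registry()`): applicant-style specs with realistic
  parameter-count profiles, ledgers equal to predictions perturbed by a
  lognormal annual forecast error, and registries with prescribed exclusion
  mixes.
- **Reference tables** (`ncpe_prediction_errors()` and friends): the
  published summary tables of a national audit of twelve reimbursed drugs,
  used as worked examples.

## Worked example

```r
library(biaval)

spec <- bia_spec(
  drug_id = "EXAMPLE",
  features = bia_features(prevalence = TRUE, population_growth = TRUE),
  prevalent_pool = 2400, growth_rate = 0.03,
  market_share = c(0.05, 0.10, 0.15, 0.18, 0.20),
  units_per_day = 1, pack_size = 28, list_price = 180
)
gross <- gross_budget_impact(spec)
gross
#> <bia_gross> drug EXAMPLE
#> # A tibble: 5 × 5
#>   drug_id  year treated packs     cost
#>   <chr>   <int>   <dbl> <dbl>    <dbl>
#> 1 EXAMPLE     1    120  1565.  281764.
#> 2 EXAMPLE     2    247. 3225.  580434.
#> 3 EXAMPLE     3    382. 4982.  896771.
#> 4 EXAMPLE     4    472. 6158. 1108409.
#> 5 EXAMPLE     5    540. 7047. 1268513.
```

Year 1: 5% of 2400 eligible patients (120) need ~13 packs each
(1 unit/day, 28-unit packs), costing ~282k at 180 per pack; uptake and
population growth carry the impact to ~1.27M by year 5.

```r
psa <- run_psa(spec, psa_config(n_simulations = 1000, seed = 42))
psa
#> <bia_psa> drug EXAMPLE: 1000 draws, uniform +/-20%, list price fixed
#> # A tibble: 5 × 4
#>    year     min     mean      max
#>   <int>   <dbl>    <dbl>    <dbl>
#> 1     1 140024.  283986.  502773.
#> 2     2 275070.  581661. 1066238.
#> 3     3 428818.  907690. 1657953.
#> 4     4 566556. 1118768. 2039104.
#> 5     5 619305. 1285812. 2463113.
```

Now pretend reality disagreed with the forecast: a synthetic ledger with 40%
lognormal annual forecast error and only 42 months of reimbursement.

```r
led <- generate_dispensing(spec, error_model(sigma = 0.4, seed = 7),
                           months_available = 42)
realised <- annual_realised(led, "EXAMPLE")
err <- prediction_error_pct(gross$per_year_cost, realised$realised)
round(err, 1)
#> [1] -27.0  -5.0  10.5 -17.9    NA
classify_drug(err[realised$full])
#> # A tibble: 1 × 3
#>   classification majority_classification n_years
#>   <chr>          <chr>                     <int>
#> 1 mixed          over                          3
classify_coverage(psa, realised)
#> # A tibble: 5 × 3
#>   drug_id  year status
#>   <chr>   <int> <chr>
#> 1 EXAMPLE     1 inside_psa_bounds
#> 2 EXAMPLE     2 inside_psa_bounds
#> 3 EXAMPLE     3 inside_psa_bounds
#> 4 EXAMPLE     4 not_available
#> 5 EXAMPLE     5 not_available
```

The model overpredicted years 1 and 2 and underpredicted year 3 (positive =
underprediction); only the three full 12-month windows are compared — year 4
is partial (42 months) and year 5 absent — and all three realised values
fell inside the PSA bounds.

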
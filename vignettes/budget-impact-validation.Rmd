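---
title: "Validating drug budget-impact models against realised utilisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating drug budget-impact models against realised utilisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biaval)
```

## The problem

When a pharmaceutical company seeks reimbursement for a new drug, its HTA
dossier includes a budget impact analysis (BIA): a forecast of the financial
consequence of adoption over a finite horizon, typically five years. Payers
rely on these forecasts for affordability decisions, yet how accurate they
turn out to be can only be judged retrospectively, by comparing the
prediction against the expenditure actually reimbursed through the claims
system. `biaval` implements that retrospective validation as a reusable
pipeline:

1. a canonical **gross drug budget-impact engine** that can express an
   applicant-style model (module `bia_spec` / `gross_budget_impact()`),
2. a **probabilistic sensitivity analysis** (PSA) that propagates parameter
   uncertainty through the model (`run_psa()`),
3. a **dispensing ledger** reader/aggregator producing annual realised
   utilisation at list price (`read_dispensing()`, `annual_realised()`),
4. **accuracy metrics**: signed prediction-error percentages, over/under
   classification, extremes, and PSA-coverage summaries,
5. the **HTA selection rules and censuses** used to assemble such an audit
   (`apply_exclusions()`, `parameter_census()`, `feature_census()`), and
6. a **synthetic-data generator** that emulates every confidential input so
   the whole pipeline can be exercised and falsified end to end.

The package also carries the published summary tables of a national audit of
twelve reimbursed drugs (`ncpe_*()` functions) as worked-example fixtures.

## The gross budget-impact model

Applicant submissions are confidential and their equations are never
published; only the *categories* of parameters they use (population, market
share, dosage, acquisition cost) and a handful of structural features are
recoverable. The engine here is therefore a single canonical multiplicative
cohort model able to carry any such profile. For model year
$y \in \{1,\dots,H\}$ (model years, not calendar years; $H = 5$ by default):

$$
\mathrm{eligible}(y) = \bigl(P\,[\mathrm{prev}] + I\,[\mathrm{inc}]\bigr)
  \,(1+g)^{y-1} \prod_j f_j
$$

with prevalent pool $P$, incident inflow $I$ (persons/year), growth rate $g$,
and optional population attrition fractions $f_j \in [0,1]$ (an
epidemiological eligibility chain). Market share $m_y$ is **point-in-year
penetration**: in the simple case, person-years on treatment are
$\mathrm{eligible}(y)\,m_y$. When discontinuation (annual rate $d$) or a
duration cap $D$ is modelled, each year's $\mathrm{eligible}(s)\,m_s$ opens a
start cohort contributing $(1-d)^{y-s}$ person-years per starter while
$y-s < D$. Annual cost is then

$$
C_y = \mathrm{treated}(y)\;\times\;
  \underbrace{\frac{u \cdot 365.25}{q}\,a}_{\text{packs/patient-year}}
  \;\times\; \pi,
$$

with daily dose $u$, pack size $q$, adherence $a$, and list price $\pi$. This
is a *gross* impact — acquisition cost of the new drug only, valued at the
publicly available list price. Cost offsets from displaced comparators,
rebates, pharmacist fees and VAT are deliberately out of scope.

Design choices worth stating explicitly:

* **Multiplicative and monotone.** The validation and PSA stages only need a
  deterministic prediction function that is monotone in every parameter;
  monotonicity is also what lets a $2^k$ corner enumeration bracket the PSA
  extremes in the tests.
* **Point-in-year shares.** Shares are treated prevalence, not cumulative
  uptake; cohort bookkeeping is engaged only when discontinuation or a
  duration cap make it meaningful. With both off the engine reduces exactly
  to $\mathrm{eligible}(y)\, m_y \times \text{packs} \times \pi$.
* **Fractional packs.** Pack demand is a population-level expectation;
  per-patient ceiling rounding is available via
  `pack_rounding = "ceil_per_patient"` but off by default.
* **365.25 days/year**, configurable through `days_per_year`.
* **Disabled features carry neutral values** (growth 0, adherence 1,
  discontinuation 0, unbounded duration), enforced at construction so a
  feature census can be read off the spec unambiguously.
* **Parameter identity.** Every field maps to exactly one parameter record
  (`spec_parameters()`); yearly shares count one per year, the
  discontinuation rate is censused under market share, adherence under
  dosage, and the duration cap is structural (an integer switch, not a
  sampled quantity).

## Probabilistic sensitivity analysis

The PSA perturbs **every parameter except the agreed list price**
independently and uniformly within ±20% of its point value (1000 draws by
default), re-evaluates the model per draw, and summarises each year by the
simulated minimum and maximum. Choices:

* **Uniform ±20% default**; symmetric triangular and truncated-normal
  variants on the same support are provided because alternative bell-shaped
  choices make little difference in practice, and a percentile-bound option
  exists for users who prefer quantiles to min/max.
* **Independent sampling** across parameters and years — no correlation
  structure is claimed or imposed.
* **Closed-interval coverage**: realised utilisation exactly on a bound
  counts as inside (a measure-zero event; inclusive is the conservative
  reading).
* **Per-draw substreams**: draw $i$ uses a seed derived deterministically
  from (seed, $i$), so raising `n_simulations` extends the draw sequence
  without reshuffling earlier draws, and sampled fractions are clamped back
  to their legal intervals after sampling.

## Realised utilisation

Claims-style ledgers record monthly dispensing. `annual_realised()` sums
list-price expenditure over consecutive 12-month windows anchored at the
month of reimbursement (first nonzero dispensing unless declared). Whether a
"year" should mean such a rolling window or a calendar year is genuinely
ambiguous in audit practice; both are implemented (`year_mode`), anchored is
the default because it matches "starting from the month of reimbursement".
Windows extending past the analysis end are masked as partial and excluded
from comparison rather than extrapolated.

## Accuracy metrics

The yearly error is $(r_y - p_y)/p_y \times 100$: positive =
underprediction. The alternative reading "prediction as a percentage of
realised" is bounded above by construction and cannot produce the error
magnitudes (e.g. +1017%) that occur in practice together with the stated
sign convention, so the signed-relative-to-prediction form is the default
and the literal variant is kept as `formula = "share_of_realised"` for
sensitivity checks. Drug-level classification is `overpredicted_all_years` /
`underpredicted_all_years` / `mixed`; a **strict-majority** classification
additionally assigns mixed drugs to a side (ties stay tied, zero errors
count to neither side), which is the only rule that reproduces a clean
six/six under/over split on the audited table.

## HTA selection and censuses

`apply_exclusions()` applies the audit's five exclusion rules in a fixed
order — no budget-impact model, multiple indications, not reimbursed for a
full year (< 12 months), hospital-only, hepatitis C indication — counting
each record under its *first* matching rule. The included set is
order-invariant (rules are record properties); the per-reason tally is not,
which is why the order is pinned. "Full year" means 12 months reimbursed at
the analysis date.

## The synthetic-data generator

The real inputs — applicant models and claims data — are confidential, so
the generator reproduces their statistical structure:

* **Specs** (`generate_spec()`): feature flags drawn from the audited
  marginals (prevalence 12/12, growth 8/12, incidence 6/12, duration 3/12,
  discontinuation 2/12, adherence 1/12), parameter counts drawn within the
  audited ranges (population 3–91, market share 5–30, dosage 1–4,
  acquisition 1–3). Counts beyond the structural fields are realised as
  multiplicative padding parameters, mirroring how applicant models build an
  eligible population from long chains of epidemiological fractions.
  Padding fractions are drawn in [0.50, 0.83]: far enough below 1 that a
  ±20% perturbation never touches the [0, 1] clamp, keeping the PSA
  symmetric around the point estimate for arbitrarily heavily parameterised
  models. The source population is back-computed through the chain so the
  year-1 eligible population always lands in the documented 100–100,000
  range; for long chains the nominal source population is correspondingly
  large, which is cosmetic — only the eligible product enters the model.
  Numeric defaults: year-5 share 5–50% with a linear ramp from 20–60% of it
  in year 1, list price 10–10,000 per pack (log-uniform), daily dose 0.5–4
  units, common pack sizes, growth 1–10%/year, adherence 70–83%,
  discontinuation 5–30%/year, duration caps 2–4 years.
* **Forecast error** (`error_model()`): realised = predicted ×
  bias × $e^{\sigma Z}$, $Z \sim N(0,1)$ drawn once per model *year* —
  annual, because the comparisons are annual; the monthly spread
  (linear launch ramp in year 1 by default, flat thereafter) is presentation
  only and preserves annual totals exactly. No distributional information
  about real forecast errors is recoverable beyond twelve drug
  trajectories; the lognormal defaults are loosely matched to that spread,
  not fitted. The shocks $Z$ depend only on the seed, not on $\sigma$, so
  runs at different noise levels are driven by common random numbers and
  noise-level comparisons are paired — the degradation properties below
  hold pathwise, not merely in expectation.
* **Registries** (`generate_registry()`): records with mutually exclusive
  exclusion attributes in requested counts, so each excluded record matches
  exactly one rule.

What passing the synthetic suites does and does not show: the generator
emulates parameter-count profiles, feature mixes, launch ramps and
multiplicative annual forecast error. It does not emulate indication mixing,
scheme-specific rebates and fees, additive subgroup structure inside
population calculations (which would narrow PSA bounds relative to a purely
multiplicative chain), or correlated errors across drugs — so green tests
demonstrate the pipeline's correctness and calibration under these stated
conditions, not the real-world accuracy of any applicant model.

## Numerical choices and degenerate inputs

* Zero sampling range (or a zero-valued parameter) collapses a draw to the
  point value; the triangular and truncated-normal samplers handle the
  degenerate interval explicitly.
* Errors are undefined for a nonpositive prediction (`prediction_error_pct()`
  errors out) and bounded below by −100%, attained exactly when nothing was
  dispensed.
* Duplicate ledger drug-months are summed; malformed months and negative
  quantities are rejected with row numbers.
* Unknown keys in spec JSON are rejected rather than ignored (schema
  versioned at "1.0").
* Census modes break ties toward the smaller count.

## Problem sizes

The shipped test suite runs the worked-example tables as-is (12 drugs), PSA
property checks at 1000 draws, a 12-drug noiseless end-to-end run, and a
noise sweep of 200 generated drugs × 1000-draw PSAs at
$\sigma \in \{0, 0.25, 0.5, 1\}$ — about a minute in total. The acceptance
script reruns the worked examples plus a 12-drug null run and a 50-drug
sweep. These sizes give stable pass/fail behaviour for the paired
(common-random-numbers) comparisons; users reproducing the sweep at other
sizes should keep the pairing.

## Known limitations

* Exact recreation of any specific audited drug model is impossible by
  design: only parameter counts and feature flags are public, so the engine
  is a canonical stand-in with those profiles.
* Purely multiplicative uncertainty propagation widens PSA bounds quickly as
  parameter counts grow; real models with additive population components
  would show narrower bounds. Coverage results for heavily parameterised
  synthetic models are therefore conservative (rarely outside).
* Net budget impact (comparator displacement), rebates/fees/VAT, and
  indication-level splitting of utilisation are out of scope throughout.
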
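# Synthetic-data generator: applicant-style model specifications with
# realistic parameter-count and feature profiles, dispensing ledgers equal to
# model predictions perturbed by a multiplicative forecast-error model, and
# HTA registries with prescribed exclusion mixes. The real submissions and
# claims data behind national audits are confidential; these generators
# reproduce their statistical structure so the whole pipeline can be
# exercised end to end.

#' Profile for generating applicant-style model specifications
#'
#' Defaults mirror the parameter-count and feature profiles observed across
#' twelve audited national HTA submissions: population parameter counts from
#' 3 to 91, market-share counts 5 to 30, dosage 1 to 4, acquisition cost 1 to
#' 3; every model built on prevalence, two thirds with population growth,
#' half with incidence, a quarter with duration of treatment, one sixth with
#' discontinuation and one twelfth with adherence.
#'
#' @param population_range,market_share_range,dosage_range,acquisition_cost_range
#'   Integer `c(min, max)` ranges for parameter counts per category.
#' @param feature_probs Named numeric marginal probabilities for the six
#'   feature flags.
#' @param pool_range Range (persons) for the year-1 eligible population,
#'   sampled log-uniformly.
#' @param share_range Range for the year-5 market share; shares ramp up
#'   linearly from a fraction of it in year 1.
#' @param price_range Range (currency/pack) for the list price, sampled
#'   log-uniformly.
#' @param horizon Model horizon in years.
#' @param seed Integer seed for [generate_spec()].
#' @return A `bia_spec_profile` list.
#' @export
spec_profile <- function(population_range = c(3L, 91L),
                         market_share_range = c(5L, 30L),
                         dosage_range = c(1L, 4L),
                         acquisition_cost_range = c(1L, 3L),
                         feature_probs = c(
                           incidence = 6 / 12, prevalence = 1,
                           population_growth = 8 / 12, adherence = 1 / 12,
                           discontinuation = 2 / 12,
                           duration_of_treatment = 3 / 12
                         ),
                         pool_range = c(100, 100000),
                         share_range = c(0.05, 0.5),
                         price_range = c(10, 10000),
                         horizon = 5L, seed = 1L) {
  ranges <- list(
    population = population_range, market_share = market_share_range,
    dosage = dosage_range, acquisition_cost = acquisition_cost_range
  )
  for (r in ranges) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1) {
      abort("count ranges must be nonempty c(min, max) with min >= 1")
    }
  }
  probs <- feature_probs[bia_feature_names]
  if (anyNA(probs) || any(probs < 0 | probs > 1)) {
    abort("feature_probs must cover all six features with values in [0, 1]")
  }
  structure(
    list(
      count_ranges = ranges, feature_probs = probs,
      pool_range = pool_range, share_range = share_range,
      price_range = price_range, horizon = as.integer(horizon),
      seed = as.integer(seed)
    ),
    class = "bia_spec_profile"
  )
}

runif_log <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

#' Generate an applicant-style model specification
#'
#' Draws feature flags from the profile's marginals (forcing a source
#' population if neither incidence nor prevalence comes up), draws parameter
#' counts within the profile ranges, and pads each category with
#' multiplicative attrition/adjustment parameters to reach the drawn count.
#' Population padding factors are eligibility-chain fractions in
#' \[0.5, 0.83\] — far enough from 1 that a +/-20% perturbation never hits
#' the \[0, 1\] clamp — and the source population is back-computed so the
#' year-1 eligible population always lands in the profile's `pool_range`.
#' Reproducible: the same profile and index always yield the same spec.
#'
#' @param profile A [spec_profile()].
#' @param index 1-based drug index; each index has its own RNG substream
#'   under `profile$seed`.
#' @param drug_id Identifier (default `"SYN-<index>"`).
#' @return A [bia_spec()].
#' @examples
#' spec <- generate_spec(spec_profile(seed = 7), index = 1)
#' parameter_census(list(spec))
#' @export
generate_spec <- function(profile, index = 1L,
                          drug_id = sprintf("SYN-%02d", index)) {
  withr::with_seed(substream_seed(profile$seed, index), {
    p <- profile$feature_probs
    flags <- runif(6) < p
    names(flags) <- bia_feature_names
    if (!flags[["incidence"]] && !flags[["prevalence"]]) {
      flags[["prevalence"]] <- TRUE
    }
    features <- do.call(bia_features, as.list(flags))
    h <- profile$horizon
    rng <- profile$count_ranges
    draw_count <- function(r) sample(seq(r[1], r[2]), 1L)
    n_pop <- draw_count(rng$population)
    n_share <- draw_count(rng$market_share)
    n_dose <- draw_count(rng$dosage)
    n_acq <- draw_count(rng$acquisition_cost)

    growth <- if (flags[["population_growth"]]) runif(1, 0.01, 0.10) else 0
    adherence <- if (flags[["adherence"]]) runif(1, 0.70, 0.83) else 1
    disc <- if (flags[["discontinuation"]]) runif(1, 0.05, 0.30) else 0
    dur <- if (flags[["duration_of_treatment"]]) sample(2:4, 1L) else Inf

    # population: eligible target first, then back out the source pool
    # through the padding chain so the product stays in pool_range
    pop_struct <- sum(flags[c("prevalence", "incidence", "population_growth")])
    n_pop <- max(n_pop, pop_struct + 0L)
    n_pop_extra <- n_pop - pop_struct
    eligible_target <- runif_log(1, profile$pool_range)
    pop_factors <- if (n_pop_extra > 0) runif(n_pop_extra, 0.50, 0.83) else numeric()
    source_total <- eligible_target / prod(c(pop_factors, 1))
    if (flags[["prevalence"]] && flags[["incidence"]]) {
      split <- runif(1, 0.2, 0.8)
      pool <- source_total * split
      inflow <- source_total * (1 - split)
    } else if (flags[["prevalence"]]) {
      pool <- source_total
      inflow <- 0
    } else {
      pool <- 0
      inflow <- source_total
    }

    share_final <- runif(1, profile$share_range[1], profile$share_range[2])
    share_start <- share_final * runif(1, 0.2, 0.6)
    market_share <- seq(share_start, share_final, length.out = h)
    share_struct <- h + flags[["discontinuation"]]
    n_share <- max(n_share, share_struct)
    n_share_extra <- n_share - share_struct
    share_factors <- if (n_share_extra > 0) {
      runif(n_share_extra, 0.50, 0.83)
    } else {
      numeric()
    }

    dose_struct <- 2L + flags[["adherence"]]
    n_dose <- max(n_dose, dose_struct)
    n_dose_extra <- n_dose - dose_struct
    dose_factors <- if (n_dose_extra > 0) runif(n_dose_extra, 0.70, 1.0) else numeric()

    n_acq_extra <- n_acq - 1L
    acq_factors <- if (n_acq_extra > 0) runif(n_acq_extra, 0.90, 1.0) else numeric()

    mk_extra <- function(values, category, what) {
      if (!length(values)) return(NULL)
      data.frame(
        name = sprintf("%s_%s_%d", category, what, seq_along(values)),
        category = category, value = values, psa_vary = TRUE,
        stringsAsFactors = FALSE
      )
    }
    extra <- do.call(rbind, Filter(Negate(is.null), list(
      mk_extra(pop_factors, "population", "fraction"),
      mk_extra(share_factors, "market_share", "fraction"),
      mk_extra(dose_factors, "dosage", "factor"),
      mk_extra(acq_factors, "acquisition_cost", "factor")
    )))

    bia_spec(
      drug_id = drug_id, horizon_years = h, features = features,
      prevalent_pool = pool, incident_inflow = inflow, growth_rate = growth,
      market_share = market_share, adherence = adherence,
      discontinuation_rate = disc, max_duration_years = dur,
      units_per_day = runif(1, 0.5, 4),
      pack_size = sample(c(7, 14, 28, 30, 60, 90), 1L),
      list_price = runif_log(1, profile$price_range),
      extra_parameters = extra
    )
  })
}

#' Multiplicative annual forecast-error model
#'
#' Realised utilisation is modelled as the prediction times
#' `bias * exp(sigma * Z)` with `Z ~ N(0, 1)` drawn once per model year —
#' a lognormal multiplicative error with median `bias`. `sigma = 0`,
#' `bias = 1` makes realised equal predicted exactly. The standard-normal
#' shocks depend only on the seed, not on `sigma`, so runs at different
#' noise levels with the same seed are driven by common random numbers.
#'
#' @param sigma Lognormal scale of the annual error (>= 0).
#' @param bias Multiplicative systematic factor (> 0; 1 = unbiased).
#' @param seed Integer seed for the shocks.
#' @return A `bia_error_model` list.
#' @export
error_model <- function(sigma = 0.5, bias = 1, seed = 1L) {
  if (sigma < 0) abort("sigma must be >= 0")
  if (bias <= 0) abort("bias must be > 0")
  structure(
    list(sigma = sigma, bias = bias, seed = as.integer(seed)),
    class = "bia_error_model"
  )
}

#' Generate a synthetic monthly dispensing ledger for a drug
#'
#' Each model year's true utilisation is the spec's predicted gross budget
#' impact perturbed by the forecast-error model, spread across that year's
#' 12 months — linearly ramping from launch during year 1 by default,
#' reflecting uptake, flat thereafter — and truncated at
#' `months_available`. Monthly expenditures sum exactly to the perturbed
#' annual totals; pack quantities are expenditure divided by the list price.
#'
#' @param spec A [bia_spec()].
#' @param error An [error_model()].
#' @param start_month Reimbursement month (`"YYYY-MM"`).
#' @param months_available Number of months of ledger to emit (>= 1).
#' @param ramp Year-1 monthly profile: `"linear"` (default) or `"flat"`.
#' @return A `bia_dispensing` tibble.
#' @examples
#' spec <- generate_spec(spec_profile(seed = 7))
#' led <- generate_dispensing(spec, error_model(sigma = 0, seed = 1),
#'                            months_available = 18)
#' annual_realised(led, spec$drug_id)  # year 2 partial, masked
#' @export
generate_dispensing <- function(spec, error, start_month = "2013-01",
                                months_available = 60L,
                                ramp = c("linear", "flat")) {
  ramp <- match.arg(ramp)
  if (months_available < 1) abort("months_available must be >= 1")
  validate_bia_spec(spec)
  predicted <- gross_cost_(spec)
  h <- spec$horizon_years
  z <- withr::with_seed(substream_seed(error$seed, 1L), rnorm(h))
  annual <- predicted * error$bias * exp(error$sigma * z)
  weights <- function(y) {
    if (y == 1L && ramp == "linear") (1:12) / sum(1:12) else rep(1 / 12, 12)
  }
  monthly <- unlist(lapply(seq_len(h), function(y) annual[y] * weights(y)))
  months_available <- min(as.integer(months_available), 12L * h)
  monthly <- monthly[seq_len(months_available)]
  start_idx <- month_to_index(start_month)
  out <- tibble(
    drug_id = spec$drug_id,
    month = index_to_month(start_idx + seq_along(monthly) - 1L),
    quantity_packs = monthly / spec$list_price,
    expenditure_list_price = monthly
  )
  structure(out, class = c("bia_dispensing", class(tibble())))
}

#' Generate an HTA registry with a prescribed exclusion mix
#'
#' Builds `total` HTA records of which exactly the requested number match
#' each exclusion reason — with mutually exclusive exclusion attributes, so
#' each excluded record matches one rule only — and the remainder are
#' eligible for inclusion.
#'
#' @param total Total number of HTA records.
#' @param counts Numeric of length 5: records per exclusion reason, in the
#'   order no_bim, multiple_indications, not_reimbursed_full_year,
#'   hospital_only, hepatitis_c. `sum(counts) <= total`.
#' @return Tibble of HTA records (see [read_registry()] for columns).
#' @examples
#' apply_exclusions(generate_registry(113, c(21, 37, 28, 10, 5)))
#' @export
generate_registry <- function(total, counts) {
  if (length(counts) != 5L) {
    abort("counts must have one entry per exclusion reason (5)")
  }
  if (any(counts < 0) || sum(counts) > total) {
    abort("exclusion counts must be nonnegative and sum to at most total")
  }
  counts <- as.integer(counts)
  base <- function(n, ...) {
    if (n == 0L) return(NULL)
    args <- list(...)
    tibble(
      has_budget_impact_model = rep(args$model %||% TRUE, n),
      n_indications = rep(args$ind %||% 1L, n),
      reimbursed = rep(args$reimb %||% TRUE, n),
      months_reimbursed = rep(args$months %||% 24L, n),
      hospital_only = rep(args$hosp %||% FALSE, n),
      hepatitis_c_indication = rep(args$hepc %||% FALSE, n)
    )
  }
  n_part <- counts[3]
  part <- base(n_part)
  if (n_part > 0L) {
    # half never reimbursed, half reimbursed under 12 months
    never <- seq_len(n_part) <= n_part %/% 2
    part$reimbursed <- !never
    part$months_reimbursed <- ifelse(never, 0L, 6L)
  }
  out <- bind_rows(
    base(counts[1], model = FALSE),
    base(counts[2], ind = 2L),
    part,
    base(counts[4], hosp = TRUE),
    base(counts[5], hepc = TRUE),
    base(total - sum(counts))
  )
  out <- tibble(hta_id = sprintf("HTA-%03d", seq_len(nrow(out))), out)
  validate_registry(out)
  out
}
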
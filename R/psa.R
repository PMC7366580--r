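# Monte-Carlo probabilistic sensitivity analysis: every parameter except the
# agreed list price is perturbed independently within +/- range_fraction of
# its point value, the gross budget impact is re-evaluated per draw, and the
# simulated per-year extremes form the uncertainty bounds that realised
# utilisation is compared against.

#' Probabilistic sensitivity analysis configuration
#'
#' @param n_simulations Number of Monte-Carlo draws (default 1000).
#' @param range_fraction Half-width of the sampling interval as a fraction of
#'   each parameter's point value (default 0.20, i.e. +/-20%).
#' @param distribution Sampling distribution on
#'   `[v(1 - range), v(1 + range)]`: `"uniform"` (default), symmetric
#'   `"triangular"` with mode at the point value, or `"normal_truncated"`
#'   (mean at the point value, sd = range/2 of it, truncated to the support).
#' @param seed Integer seed; each draw uses a deterministic substream derived
#'   from it, so increasing `n_simulations` extends rather than reshuffles
#'   the draw sequence.
#' @param vary_list_price Vary the list price too? `FALSE` by default — the
#'   agreed price is treated as known.
#' @param bounds `"minmax"` (default) uses the simulated per-year minimum and
#'   maximum as bounds; `"percentile"` uses symmetric quantiles.
#' @param percentile Central mass for percentile bounds (default 0.95).
#' @return A `bia_psa_config` list.
#' @export
psa_config <- function(n_simulations = 1000L, range_fraction = 0.20,
                       distribution = c("uniform", "triangular",
                                        "normal_truncated"),
                       seed = 1L, vary_list_price = FALSE,
                       bounds = c("minmax", "percentile"),
                       percentile = 0.95) {
  distribution <- match.arg(distribution)
  bounds <- match.arg(bounds)
  if (n_simulations < 1) abort("n_simulations must be >= 1")
  if (range_fraction < 0) abort("range_fraction must be >= 0")
  if (range_fraction >= 1) {
    abort("range_fraction must be < 1 (parameters need positive support)")
  }
  structure(
    list(
      n_simulations = as.integer(n_simulations),
      range_fraction = range_fraction,
      distribution = distribution,
      seed = as.integer(seed),
      vary_list_price = isTRUE(vary_list_price),
      bounds = bounds,
      percentile = percentile
    ),
    class = "bia_psa_config"
  )
}

# Vectorised draw on [v(1-r), v(1+r)] per element of v. Degenerate intervals
# (r = 0 or v = 0) return v unchanged.
draw_interval <- function(v, range_fraction, distribution) {
  n <- length(v)
  if (n == 0L) return(v)
  lo <- v * (1 - range_fraction)
  hi <- v * (1 + range_fraction)
  w <- hi - lo
  if (range_fraction == 0) return(v)
  u <- runif(n)
  out <- switch(distribution,
    uniform = lo + u * w,
    triangular = ifelse(u < 0.5,
                        lo + sqrt(u / 2) * w / 1,
                        hi - sqrt((1 - u) / 2) * w),
    normal_truncated = {
      sd <- range_fraction * v / 2
      plo <- pnorm(lo, mean = v, sd = sd)
      phi <- pnorm(hi, mean = v, sd = sd)
      qnorm(plo + u * (phi - plo), mean = v, sd = sd)
    }
  )
  ifelse(w == 0, v, out)
}

# Triangular inverse CDF above compresses to: lo + w*sqrt(u/2) on the lower
# half, hi - w*sqrt((1-u)/2) on the upper half (symmetric, mode at v).

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# One sampled spec; assumes the RNG state is already positioned (callers wrap
# in withr::with_seed on the draw's substream).
sample_spec_fields <- function(spec, config) {
  r <- config$range_fraction
  d <- config$distribution
  s <- spec
  f <- spec$features
  if (f[["prevalence"]]) {
    s$prevalent_pool <- max(0, draw_interval(spec$prevalent_pool, r, d))
  }
  if (f[["incidence"]]) {
    s$incident_inflow <- max(0, draw_interval(spec$incident_inflow, r, d))
  }
  if (f[["population_growth"]]) {
    s$growth_rate <- max(-1, draw_interval(spec$growth_rate, r, d))
  }
  s$market_share <- clamp(draw_interval(spec$market_share, r, d), 0, 1)
  if (f[["adherence"]]) {
    s$adherence <- clamp(draw_interval(spec$adherence, r, d),
                         .Machine$double.eps, 1)
  }
  if (f[["discontinuation"]]) {
    s$discontinuation_rate <- clamp(
      draw_interval(spec$discontinuation_rate, r, d), 0, 1 - 1e-12
    )
  }
  s$units_per_day <- max(0, draw_interval(spec$units_per_day, r, d))
  s$pack_size <- max(.Machine$double.eps,
                     draw_interval(spec$pack_size, r, d))
  if (config$vary_list_price) {
    s$list_price <- max(0, draw_interval(spec$list_price, r, d))
  }
  ex <- spec$extra_parameters
  if (nrow(ex)) {
    idx <- which(ex$psa_vary)
    if (length(idx)) {
      v <- draw_interval(ex$value[idx], r, d)
      frac <- ex$category[idx] %in% c("population", "market_share")
      v[frac] <- clamp(v[frac], 0, 1)
      v[!frac] <- pmax(0, v[!frac])
      s$extra_parameters$value[idx] <- v
    }
  }
  s
}

#' Draw one sampled model specification
#'
#' Replaces every parameter with `psa_vary = TRUE` by an independent draw
#' from the configured distribution on `[v(1 - range), v(1 + range)]` around
#' its point value `v`; per-year market shares are drawn independently, the
#' list price is untouched unless `vary_list_price`, and fractions are
#' clamped back to their legal interval after sampling. Draw `draw_index`
#' always yields the same spec for a given `config$seed`, independent of how
#' many other draws are taken.
#'
#' @param spec A [bia_spec()].
#' @param config A [psa_config()].
#' @param draw_index 1-based index of the Monte-Carlo draw.
#' @return A sampled `bia_spec`.
#' @export
sample_spec <- function(spec, config, draw_index = 1L) {
  validate_bia_spec(spec)
  out <- withr::with_seed(
    substream_seed(config$seed, draw_index),
    sample_spec_fields(spec, config)
  )
  validate_bia_spec(out)
  out
}

#' Run a probabilistic sensitivity analysis
#'
#' Evaluates [gross_budget_impact()] on `n_simulations` sampled specs and
#' summarises the simulated annual costs by element-wise minimum, mean and
#' maximum (or symmetric percentiles, per the config). Fully reproducible for
#' a fixed seed.
#'
#' @param spec A [bia_spec()].
#' @param config A [psa_config()].
#' @return A `bia_psa` object: `drug_id`, `per_year_draws`
#'   (`n_simulations x horizon` matrix), `per_year_min`, `per_year_mean`,
#'   `per_year_max`, `deterministic` (unsampled cost vector), and the config.
#' @examples
#' spec <- bia_spec("A", prevalent_pool = 1000, market_share = 0.1,
#'                  units_per_day = 1, pack_size = 30, list_price = 100)
#' psa <- run_psa(spec, psa_config(n_simulations = 200, seed = 42))
#' psa
#' @export
run_psa <- function(spec, config = psa_config()) {
  validate_bia_spec(spec)
  n <- config$n_simulations
  h <- spec$horizon_years
  draws <- matrix(NA_real_, nrow = n, ncol = h)
  for (i in seq_len(n)) {
    si <- withr::with_seed(
      substream_seed(config$seed, i),
      sample_spec_fields(spec, config)
    )
    draws[i, ] <- gross_cost_(si)
  }
  if (config$bounds == "percentile") {
    a <- (1 - config$percentile) / 2
    lo <- apply(draws, 2, quantile, probs = a, names = FALSE)
    hi <- apply(draws, 2, quantile, probs = 1 - a, names = FALSE)
  } else {
    lo <- apply(draws, 2, min)
    hi <- apply(draws, 2, max)
  }
  structure(
    list(
      drug_id = spec$drug_id,
      per_year_draws = draws,
      per_year_min = lo,
      per_year_mean = colMeans(draws),
      per_year_max = hi,
      deterministic = gross_cost_(spec),
      config = config
    ),
    class = "bia_psa"
  )
}

#' @export
print.bia_psa <- function(x, ...) {
  cat(sprintf(
    "<bia_psa> drug %s: %d draws, %s +/-%g%%, list price %s\n",
    x$drug_id, x$config$n_simulations, x$config$distribution,
    100 * x$config$range_fraction,
    if (x$config$vary_list_price) "varied" else "fixed"
  ))
  print(tibble(
    year = seq_along(x$per_year_min),
    min = x$per_year_min,
    mean = x$per_year_mean,
    max = x$per_year_max
  ))
  invisible(x)
}

#' Classify realised utilisation against PSA bounds
#'
#' For each model year with a full realised value r: `inside_psa_bounds` iff
#' `min <= r <= max` (closed interval), otherwise `outside_psa_bounds`; years
#' without a full 12-month realised window are `not_available`.
#'
#' @param psa A `bia_psa` from [run_psa()].
#' @param realised A `bia_realised` series from [annual_realised()] for the
#'   same drug.
#' @return Tibble with columns `drug_id`, `year`, `status` (one of
#'   `inside_psa_bounds`, `outside_psa_bounds`, `not_available`).
#' @export
classify_coverage <- function(psa, realised) {
  if (nrow(realised) && !identical(unique(realised$drug_id), psa$drug_id)) {
    abort(sprintf(
      "drug mismatch: PSA is for %s, realised series for %s",
      psa$drug_id, paste(unique(realised$drug_id), collapse = ", ")
    ))
  }
  h <- length(psa$per_year_min)
  status <- rep("not_available", h)
  for (y in seq_len(h)) {
    row <- realised[realised$year == y, ]
    if (nrow(row) == 1L && isTRUE(row$full) && !is.na(row$realised)) {
      inside <- row$realised >= psa$per_year_min[y] &&
        row$realised <= psa$per_year_max[y]
      status[y] <- if (inside) "inside_psa_bounds" else "outside_psa_bounds"
    }
  }
  tibble(drug_id = psa$drug_id, year = seq_len(h), status = status)
}
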
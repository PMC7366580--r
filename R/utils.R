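# Internal helpers shared across modules.

# Deterministic per-draw RNG substream: changing the number of draws must not
# reshuffle earlier draws, so each draw i gets its own seed derived from
# (seed, i). Kept strictly below 2^31 - 1.
substream_seed <- function(seed, index) {
  seed <- as.numeric(seed) %% 65011
  index <- as.numeric(index)
  as.integer((seed * 33029 + index * 7919 + 1) %% 2147483647)
}

# "YYYY-MM" <-> absolute month index (months since year 0). The index form
# makes 12-month window arithmetic trivial.
month_to_index <- function(month) {
  ok <- grepl("^\\d{4}-(0[1-9]|1[0-2])$", month)
  if (!all(ok)) {
    abort(sprintf(
      "invalid month(s), expected 'YYYY-MM': %s",
      paste(unique(month[!ok]), collapse = ", ")
    ))
  }
  yr <- as.integer(substr(month, 1, 4))
  mo <- as.integer(substr(month, 6, 7))
  yr * 12L + (mo - 1L)
}

index_to_month <- function(index) {
  sprintf("%04d-%02d", index %/% 12L, index %% 12L + 1L)
}

# Most frequent value; ties broken towards the smallest, NA dropped.
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
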
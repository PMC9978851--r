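# Internal helpers: day-of-year arithmetic, condition constructors, RNG scoping.

# Fractional day-of-year of a POSIXct timestamp, 1-based (midnight Jan 1 -> 1.0),
# resolved to the nearest minute.
doy_fraction <- function(time) {
  lt <- as.POSIXlt(time)
  mins <- round(lt$hour * 60 + lt$min + lt$sec / 60)
  lt$yday + 1 + mins / 1440
}

timestamp_year <- function(time) as.POSIXlt(time)$year + 1900L

# Inverse of doy_fraction for simulation output (ISO-8601, minute resolution).
doy_to_timestamp <- function(year, doy) {
  origin <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC")
  format(origin + round((doy - 1) * 1440) * 60, "%Y-%m-%dT%H:%M:%S")
}

abort_format <- function(msg, ...) abort(msg, class = "phenofrass_format_error", ...)
abort_validation <- function(msg, ...) abort(msg, class = "phenofrass_validation_error", ...)
abort_parameter <- function(msg, ...) abort(msg, class = "phenofrass_parameter_error", ...)
abort_numerical <- function(msg, ...) abort(msg, class = "phenofrass_numerical_error", ...)

# Run code under a temporary RNG state so package internals never disturb the
# caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a per-unit child seed from one master seed, kept inside 32-bit range.
child_seed <- function(seed, index) {
  (as.integer(seed) + 48271L * as.integer(index)) %% 2147483111L
}

# Integer doys whose midnight falls inside [start, end); a sub-daily interval
# that straddles no midnight uses its single covering doy.
doys_in_interval <- function(start, end) {
  lo <- ceiling(start)
  hi <- ceiling(end) - 1
  if (lo > hi) return(floor(start))
  lo:hi
}

# Fraction of day d (the span [d, d+1)) covered by [start, end), per day.
day_coverage <- function(doys, start, end) {
  pmin(pmax(pmin(end, doys + 1) - pmax(start, doys), 0), 1)
}
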
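# Internal helpers shared across modules.

SECONDS_PER_DAY <- 86400

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derived from a global seed and a stage name,
# kept strictly below 2^31 so it is a valid R integer seed.
derive_seed <- function(global_seed, stage) {
  h <- 0
  for (c in utf8ToInt(stage)) h <- (h * 131 + c) %% 1000003
  as.integer((as.numeric(global_seed) %% 65521) * 32749 + h) %% 2147483647L
}

# UTC calendar date as integer days since epoch; the package's single
# configured timezone offset (seconds) is applied before flooring.
search_date <- function(ts, tz_offset_s = 0) {
  as.integer(floor((ts + tz_offset_s) / SECONDS_PER_DAY))
}

# calendar month key "YYYY-MM" for epoch-second timestamps
month_key <- function(ts, tz_offset_s = 0) {
  format(as.POSIXct(ts + tz_offset_s, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m")
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("%s must be a probability in [0, 1]", name), call. = FALSE)
}

check_latlon <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180))
    stop("latitude must lie in [-90, 90] and longitude in [-180, 180]",
         call. = FALSE)
  invisible(TRUE)
}

split_tokens <- function(tokens) strsplit(tokens, " ", fixed = TRUE)
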
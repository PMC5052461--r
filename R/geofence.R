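#' Geofence and cohort-filter policy
#'
#' Thresholds of the visit-detection and inclusion/exclusion rules: a visit
#' is a contiguous in-fence run of searches within `radius_m` of one facility
#' whose first-to-last span is at least `min_dwell_s`; users with more than
#' `max_monthly_proximal_searches` facility-proximal searches in any calendar
#' month, or searches near more than `max_monthly_distinct_facilities`
#' distinct facilities in any calendar month, are excluded; patients need at
#' least `min_history_days` distinct search days strictly before their
#' endpoint visit. A run breaks when more than `max_run_gap_s` elapses
#' between consecutive in-fence searches (prevents day-spanning phantom
#' dwells).
#'
#' @param radius_m geofence radius, meters
#' @param min_dwell_s minimum dwell, seconds
#' @param max_monthly_proximal_searches monthly cap on facility-proximal
#'   searches (counted near any facility)
#' @param max_monthly_distinct_facilities monthly cap on distinct proximal
#'   facilities
#' @param min_history_days required distinct search days before the endpoint
#' @param earth_radius_m sphere radius for great-circle distances
#' @param max_run_gap_s maximum gap between consecutive in-fence searches of
#'   one visit run
#' @param endpoint `"first"` (default) or `"last"` facility visit as the
#'   patient endpoint
#' @param tz_offset_s timezone offset applied before day/month bucketing
#' @return a `geofence_policy` list
#' @export
geofence_policy <- function(radius_m = 200,
                            min_dwell_s = 900,
                            max_monthly_proximal_searches = 15L,
                            max_monthly_distinct_facilities = 5L,
                            min_history_days = 42L,
                            earth_radius_m = 6371000,
                            max_run_gap_s = 21600,
                            endpoint = c("first", "last"),
                            tz_offset_s = 0) {
  vals <- c(radius_m, min_dwell_s, max_monthly_proximal_searches,
            max_monthly_distinct_facilities, min_history_days,
            earth_radius_m, max_run_gap_s)
  if (any(vals <= 0)) stop("all policy thresholds must be > 0", call. = FALSE)
  pol <- list(radius_m = radius_m, min_dwell_s = min_dwell_s,
              max_monthly_proximal_searches =
                as.integer(max_monthly_proximal_searches),
              max_monthly_distinct_facilities =
                as.integer(max_monthly_distinct_facilities),
              min_history_days = as.integer(min_history_days),
              earth_radius_m = earth_radius_m,
              max_run_gap_s = max_run_gap_s,
              endpoint = match.arg(endpoint),
              tz_offset_s = tz_offset_s)
  class(pol) <- "geofence_policy"
  pol
}

#' Great-circle distance between coordinate pairs
#'
#' Haversine formula on a sphere (default radius 6,371,000 m). Vectorized and
#' symmetric; one tenth of a milli-degree of latitude is about 11 m.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees
#' @param earth_radius_m sphere radius in meters
#' @return distance(s) in meters
#' @export
haversine_distance <- function(lat1, lon1, lat2, lon2,
                               earth_radius_m = 6371000) {
  check_latlon(lat1, lon1)
  check_latlon(lat2, lon2)
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * earth_radius_m * asin(pmin(1, sqrt(a)))
}

# nearest facility within the geofence radius for every record (NA outside)
.nearest_fence <- function(records, facilities, policy) {
  n <- nrow(records)
  best_d <- rep(Inf, n)
  best_f <- rep(NA_character_, n)
  for (j in seq_len(nrow(facilities))) {
    d <- haversine_distance(records$lat, records$lon,
                            facilities$lat[j], facilities$lon[j],
                            policy$earth_radius_m)
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_f[upd] <- facilities$facility_id[j]
  }
  best_f[best_d > policy$radius_m] <- NA_character_
  best_f
}

#' Detect putative facility visits from log geometry and dwell time
#'
#' Contiguous runs of a user's time-sorted searches inside the geofence of
#' one facility form candidate visit events; the dwell is the span from the
#' run's first to last timestamp, and events dwelling less than
#' `policy$min_dwell_s` are discarded.
#'
#' @param records search records (user_id, ts, lat, lon, ...)
#' @param facilities facility gazetteer (facility_id, lat, lon)
#' @param policy a [geofence_policy()]
#' @return `data.table` of visit events: user_id, facility_id, entry_time,
#'   dwell_s, n_searches_in_fence
#' @export
detect_facility_visits <- function(records, facilities,
                                   policy = geofence_policy()) {
  if (is.null(facilities) || nrow(facilities) == 0)
    stop("facility list is empty", call. = FALSE)
  rec <- data.table::as.data.table(records)
  data.table::setorder(rec, user_id, ts)
  rec$fence <- .nearest_fence(rec, facilities, policy)
  rec$row <- seq_len(nrow(rec))

  inf <- rec[!is.na(fence)]
  if (nrow(inf) == 0)
    return(data.table::data.table(user_id = character(),
                                  facility_id = character(),
                                  entry_time = numeric(), dwell_s = numeric(),
                                  n_searches_in_fence = integer()))
  # a run breaks on user change, facility change, any out-of-fence search in
  # between, or a long time gap
  new_run <- c(TRUE, inf$user_id[-1] != inf$user_id[-nrow(inf)] |
                 inf$fence[-1] != inf$fence[-nrow(inf)] |
                 diff(inf$ts) > policy$max_run_gap_s |
                 diff(inf$row) > 1L)
  inf$run_id <- cumsum(new_run)
  ev <- inf[, .(user_id = user_id[1], facility_id = fence[1],
                entry_time = ts[1], dwell_s = ts[.N] - ts[1],
                n_searches_in_fence = .N), by = "run_id"]
  ev <- ev[ev$dwell_s >= policy$min_dwell_s, ]
  ev$run_id <- NULL
  ev[]
}

# facility-proximal searches per record (within radius of any facility)
.proximal_flags <- function(records, facilities, policy) {
  !is.na(.nearest_fence(records, facilities, policy))
}

#' Apply the cohort inclusion/exclusion filters
#'
#' Retains users that (i) have at least one retained visit event, (ii) never
#' exceed the monthly facility-proximal search cap, (iii) never search near
#' more than the allowed number of distinct facilities in a calendar month,
#' and (iv) have at least `min_history_days` distinct search days strictly
#' before their endpoint visit date.
#'
#' @param visits events from [detect_facility_visits()]
#' @param records all search records
#' @param facilities facility gazetteer
#' @param policy a [geofence_policy()]
#' @return `data.table` of retained patients: user_id, endpoint_time
#'   (start-of-day epoch seconds of the visit date), first_visit_time
#' @export
apply_cohort_filters <- function(visits, records, facilities,
                                 policy = geofence_policy()) {
  rec <- data.table::as.data.table(records)
  if (nrow(visits) == 0)
    return(data.table::data.table(user_id = character(),
                                  endpoint_time = numeric(),
                                  visit_time = numeric()))
  rec$fence <- .nearest_fence(rec, facilities, policy)
  prox <- rec[!is.na(fence)]
  prox$month <- month_key(prox$ts, policy$tz_offset_s)

  by_month <- prox[, .(n = .N, nfac = length(unique(fence))),
                   by = c("user_id", "month")]
  bad_count <- unique(by_month$user_id[
    by_month$n > policy$max_monthly_proximal_searches])
  bad_fac <- unique(by_month$user_id[
    by_month$nfac > policy$max_monthly_distinct_facilities])

  vt <- visits[, .(visit_time = if (policy$endpoint == "first")
    min(entry_time) else max(entry_time)), by = "user_id"]
  vt$endpoint_time <- search_date(vt$visit_time, policy$tz_offset_s) *
    SECONDS_PER_DAY - policy$tz_offset_s

  rec$date <- search_date(rec$ts, policy$tz_offset_s)
  hist_days <- rec[vt, on = "user_id"][ts < endpoint_time,
                                       .(n_days = length(unique(date))),
                                       by = "user_id"]
  enough <- hist_days$user_id[hist_days$n_days >= policy$min_history_days]

  keep <- setdiff(intersect(vt$user_id, enough), union(bad_count, bad_fac))
  out <- vt[vt$user_id %in% keep, c("user_id", "endpoint_time", "visit_time")]
  data.table::setorder(out, user_id)
  out[]
}

#' Sample controls matched on the number of search days
#'
#' The candidate pool is every user with no retained visit event. One control
#' is drawn per patient, matched exactly on the patient's count of distinct
#' search days where possible and to the nearest available count otherwise
#' (recorded in the `matched_exactly` column).
#'
#' @param records all search records
#' @param visits events from [detect_facility_visits()]
#' @param patients retained patients from [apply_cohort_filters()]
#' @param policy a [geofence_policy()]
#' @param seed integer seed
#' @return `data.table`: user_id, matched_patient, n_days, matched_exactly
#' @export
sample_controls <- function(records, visits, patients,
                            policy = geofence_policy(), seed = 1L) {
  rec <- data.table::as.data.table(records)
  rec$date <- search_date(rec$ts, policy$tz_offset_s)
  day_counts <- rec[, .(n_days = length(unique(date))), by = "user_id"]
  pool <- day_counts[!(day_counts$user_id %in% unique(visits$user_id)) &
                       !(day_counts$user_id %in% patients$user_id), ]
  if (nrow(pool) < nrow(patients))
    stop(sprintf(
      "control pool too small: %d candidates for %d patients (short by %d)",
      nrow(pool), nrow(patients), nrow(patients) - nrow(pool)),
      call. = FALSE)

  pat_days <- day_counts[match(patients$user_id, day_counts$user_id), ]
  with_seed(seed, {
    pool <- pool[sample.int(nrow(pool)), ]   # seeded shuffle, then greedy
    taken <- logical(nrow(pool))
    out <- vector("list", nrow(pat_days))
    for (i in seq_len(nrow(pat_days))) {
      want <- pat_days$n_days[i]
      avail <- which(!taken)
      j <- avail[which.min(abs(pool$n_days[avail] - want))]
      taken[j] <- TRUE
      out[[i]] <- data.table::data.table(
        user_id = pool$user_id[j],
        matched_patient = pat_days$user_id[i],
        n_days = pool$n_days[j],
        matched_exactly = pool$n_days[j] == want)
    }
    res <- data.table::rbindlist(out)
    if (any(!res$matched_exactly))
      message(sprintf("sample_controls: %d of %d controls matched to nearest",
                      sum(!res$matched_exactly), nrow(res)))
    res[]
  })
}
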
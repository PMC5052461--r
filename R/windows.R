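#' Partition one user's log into a 41-search-day analysis window
#'
#' Day indices count *search days* (distinct calendar dates with at least one
#' search), not calendar days, backwards from the endpoint: day 1 is the
#' search day closest to the endpoint, day 41 the furthest. For patients the
#' endpoint is the start of the visit date, so the visit day itself is
#' excluded; every record in the window is strictly before the endpoint.
#'
#' @param records one user's search records
#' @param endpoint_time epoch seconds; records at/after this time are excluded
#' @param label `"patient"` or `"control"`
#' @param n_days window length in search days (41)
#' @param tz_offset_s timezone offset for day bucketing
#' @return an `analysis_window`: list with `user_id`, `label`,
#'   `endpoint_time` and `records` (with a `day_index` column in 1..41)
#' @export
partition_window <- function(records, endpoint_time,
                             label = c("patient", "control"),
                             n_days = 41L, tz_offset_s = 0) {
  label <- match.arg(label)
  rec <- data.table::as.data.table(records)
  if (length(unique(rec$user_id)) != 1L)
    stop("partition_window expects records of exactly one user",
         call. = FALSE)
  rec <- rec[rec$ts < endpoint_time, ]
  rec$date <- search_date(rec$ts, tz_offset_s)
  dates <- sort(unique(rec$date), decreasing = TRUE)
  if (length(dates) < n_days)
    stop(structure(class = c("geoseek_insufficient_history", "error",
                             "condition"),
                   list(message = sprintf(
                     "user %s has %d search days before the endpoint; %d required",
                     rec$user_id[1], length(dates), n_days),
                     call = sys.call())))
  keep <- dates[seq_len(n_days)]
  rec <- rec[rec$date %in% keep, ]
  rec$day_index <- match(rec$date, keep)   # 1 = closest to the endpoint
  data.table::setorder(rec, ts)
  out <- list(user_id = rec$user_id[1], label = label,
              endpoint_time = endpoint_time, n_days = as.integer(n_days),
              records = rec)
  class(out) <- "analysis_window"
  out
}

#' @export
#' @method print analysis_window
print.analysis_window <- function(x, ...) {
  cat(sprintf("<analysis_window> user %s (%s), %d days, %d searches\n",
              x$user_id, x$label, x$n_days, nrow(x$records)))
  invisible(x)
}

#' Build the full cohort of analysis windows
#'
#' Runs visit detection, the inclusion/exclusion filters, matched control
#' sampling and windowing in one call. Control endpoints are picked (seeded)
#' uniformly among the control's search days that have at least `n_days`
#' distinct search days strictly before them. Users with insufficient
#' history are dropped and counted in the attributes.
#'
#' @param records all search records
#' @param facilities facility gazetteer
#' @param policy a [geofence_policy()]
#' @param seed integer seed (control sampling and endpoints)
#' @param n_days window length (default 41)
#' @return a `search_windows` object: list with `records` (stacked window
#'   records with user_id, label, day_index) and `cohort` (user_id, label,
#'   endpoint_time, n_search_days)
#' @export
build_cohort <- function(records, facilities, policy = geofence_policy(),
                         seed = 1L, n_days = 41L) {
  visits <- detect_facility_visits(records, facilities, policy)
  patients <- apply_cohort_filters(visits, records, facilities, policy)
  controls <- sample_controls(records, visits, patients, policy, seed = seed)

  rec <- data.table::as.data.table(records)
  data.table::setorder(rec, user_id, ts)
  rec_by_user <- split(rec, by = "user_id")

  wins <- list()
  dropped <- character()
  for (i in seq_len(nrow(patients))) {
    uid <- patients$user_id[i]
    w <- tryCatch(
      partition_window(rec_by_user[[uid]], patients$endpoint_time[i],
                       "patient", n_days, policy$tz_offset_s),
      geoseek_insufficient_history = function(e) NULL)
    if (is.null(w)) dropped <- c(dropped, uid) else wins[[uid]] <- w
  }

  ctrl_seed <- derive_seed(seed, "control_endpoints")
  with_seed(ctrl_seed, {
    for (i in seq_len(nrow(controls))) {
      uid <- controls$user_id[i]
      ur <- rec_by_user[[uid]]
      dates <- sort(unique(search_date(ur$ts, policy$tz_offset_s)))
      eligible <- dates[seq_along(dates) > n_days]  # >= n_days prior days
      if (length(eligible) == 0L) { dropped <- c(dropped, uid); next }
      ep_date <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
      ep_time <- ep_date * SECONDS_PER_DAY - policy$tz_offset_s
      wins[[uid]] <- partition_window(ur, ep_time, "control", n_days,
                                      policy$tz_offset_s)
    }
  })

  stacked <- data.table::rbindlist(lapply(wins, function(w) {
    r <- data.table::copy(w$records)
    r$label <- w$label
    r
  }))
  cohort <- data.table::rbindlist(lapply(wins, function(w)
    data.table::data.table(user_id = w$user_id, label = w$label,
                           endpoint_time = w$endpoint_time,
                           n_search_days = w$n_days)))
  out <- list(records = stacked, cohort = cohort, n_days = as.integer(n_days))
  attr(out, "dropped") <- dropped
  class(out) <- "search_windows"
  out
}

#' @export
#' @method print search_windows
print.search_windows <- function(x, ...) {
  cat(sprintf("<search_windows> %d users (%d patients, %d controls), %d-day windows\n",
              nrow(x$cohort), sum(x$cohort$label == "patient"),
              sum(x$cohort$label == "control"), x$n_days))
  invisible(x)
}

# coerce a single analysis_window to the stacked form used by the feature
# engine
as_search_windows <- function(w) {
  if (inherits(w, "search_windows")) return(w)
  stopifnot(inherits(w, "analysis_window"))
  r <- data.table::copy(w$records)
  r$label <- w$label
  out <- list(records = r,
              cohort = data.table::data.table(
                user_id = w$user_id, label = w$label,
                endpoint_time = w$endpoint_time, n_search_days = w$n_days),
              n_days = w$n_days)
  class(out) <- "search_windows"
  out
}
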
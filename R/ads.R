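#' Conversion-labeling policy
#'
#' A user converts when some ad impression from facility F is followed by a
#' visit to F within `lookahead_days` (default 14, "two weeks") and the user
#' had no visit to F within `lookback_days` (default 30, "one month") before
#' that visit — i.e. the visit is a new utilization, not a readmission.
#' `window_T` is the person count of the local show-conversion-rate window;
#' it has no canonical value and must be chosen by the analyst.
#'
#' @param lookback_days readmission exclusion window, days
#' @param lookahead_days attribution window after the impression, days
#' @param window_T person window for [local_show_conversion_rate()]
#' @return a `conversion_policy` list
#' @export
conversion_policy <- function(lookback_days = 30, lookahead_days = 14,
                              window_T = 101L) {
  if (lookback_days <= 0 || lookahead_days <= 0 || window_T <= 0)
    stop("lookback_days, lookahead_days and window_T must be > 0",
         call. = FALSE)
  pol <- list(lookback_days = lookback_days, lookahead_days = lookahead_days,
              window_T = as.integer(window_T))
  class(pol) <- "conversion_policy"
  pol
}

#' Label users as converted or not
#'
#' Applies the two-condition rule of [conversion_policy()] to an impression
#' stream and a visit table. The result is invariant to the order of the
#' impression rows.
#'
#' @param impressions table with user_id, facility_id, shown_time
#' @param visits table with user_id, facility_id, entry_time
#' @param policy a [conversion_policy()]
#' @return `data.table` with one row per user appearing in `impressions`:
#'   user_id, converted (0/1)
#' @export
label_conversions <- function(impressions, visits,
                              policy = conversion_policy()) {
  imp <- data.table::as.data.table(impressions)
  vis <- data.table::as.data.table(visits)
  ahead <- policy$lookahead_days * SECONDS_PER_DAY
  back <- policy$lookback_days * SECONDS_PER_DAY

  conv_users <- character()
  if (nrow(imp) && nrow(vis)) {
    j <- imp[vis, on = c("user_id", "facility_id"),
             allow.cartesian = TRUE, nomatch = NULL]
    # j: one row per (impression, visit) pair of the same user and facility
    j <- j[j$entry_time > j$shown_time &
             j$entry_time <= j$shown_time + ahead, ]
    if (nrow(j)) {
      # condition (1): no earlier visit to the same facility within the
      # lookback window before the candidate visit
      vis2 <- vis[, .(user_id, facility_id, prior_time = entry_time)]
      jj <- vis2[j, on = c("user_id", "facility_id"),
                 allow.cartesian = TRUE]
      jj$blocked <- !is.na(jj$prior_time) &
        jj$prior_time < jj$entry_time &
        jj$prior_time >= jj$entry_time - back
      # a candidate converts if no blocking prior visit exists for it
      blocked_any <- jj[, .(blocked = any(blocked)),
                        by = c("user_id", "shown_time", "entry_time")]
      conv_users <- unique(blocked_any$user_id[!blocked_any$blocked])
    }
  }
  out <- data.table::data.table(user_id = sort(unique(imp$user_id)))
  out$converted <- as.integer(out$user_id %in% conv_users)
  out[]
}

#' Local show conversion rate curve
#'
#' Users are ranked by predicted score (ties broken by user id); the local
#' rate for the user at rank r is the mean conversion flag over ranks
#' \eqn{[r - \lfloor T/2 \rfloor, r + \lfloor T/2 \rfloor]}, truncated at the
#' ends of the ranking. The curve is indexed by score percentile (rank / n).
#'
#' @param scored_users table with user_id, score in \[0, 1\], converted (0/1)
#' @param T person-window size (default from [conversion_policy()])
#' @return `data.table` sorted by rank: user_id, score, converted,
#'   percentile, local_rate
#' @export
local_show_conversion_rate <- function(scored_users, T = 101L) {
  su <- data.table::as.data.table(scored_users)
  if (nrow(su) == 0) stop("empty population", call. = FALSE)
  if (any(su$score < 0 | su$score > 1))
    stop("scores must lie in [0, 1]", call. = FALSE)
  data.table::setorder(su, score, user_id)
  n <- nrow(su)
  half <- floor(T / 2)
  cs <- cumsum(su$converted)
  r <- seq_len(n)
  lo <- pmax(1L, r - half)
  hi <- pmin(n, r + half)
  cs0 <- c(0, cs)                  # cs0[r] = conversions among ranks < r
  su$local_rate <- (cs0[hi + 1] - cs0[lo]) / (hi - lo + 1)
  su$percentile <- r / n
  su[]
}

#' Map a predicted score to an ad-bid coefficient
#'
#' Linear, monotone map of scores in \[0, 1\] onto the coefficient interval
#' \[`lower`, `upper`\] (default \[0.7, 1.3\]): `lower + (upper - lower) *
#' score`. Any monotone alternative can be supplied to the pipeline via
#' configuration.
#'
#' @param score predicted utilization score(s) in \[0, 1\]
#' @param lower,upper coefficient interval endpoints
#' @return coefficient(s)
#' @export
score_to_coefficient <- function(score, lower = 0.7, upper = 1.3) {
  if (any(score < 0 | score > 1))
    stop("scores must lie in [0, 1]", call. = FALSE)
  lower + (upper - lower) * score
}

#' A/B relative-change metrics
#'
#' Show conversion rate per group is conversions divided by impressions;
#' cost per action (CPA) is total cost divided by conversions. Reported
#' numbers are the relative change of the treated group B versus the control
#' group A, in percent: `100 * (B - A) / A`.
#'
#' @param group_a,group_b impression-level tables for the control and treated
#'   groups, each with columns `cost` and `converted` (0/1 per impression)
#' @return list with `conversion_change_pct`, `cpa_change_pct`, the per-group
#'   rates/CPAs, and `cpa_defined` (FALSE when a group has no conversions,
#'   in which case the CPA change is `NA`)
#' @export
ab_metrics <- function(group_a, group_b) {
  ga <- data.table::as.data.table(group_a)
  gb <- data.table::as.data.table(group_b)
  if (nrow(ga) == 0 || nrow(gb) == 0)
    stop("both groups need impressions", call. = FALSE)
  rate_a <- mean(ga$converted)
  rate_b <- mean(gb$converted)
  cpa_ok <- sum(ga$converted) > 0 && sum(gb$converted) > 0
  cpa_a <- if (sum(ga$converted) > 0) sum(ga$cost) / sum(ga$converted) else NA
  cpa_b <- if (sum(gb$converted) > 0) sum(gb$cost) / sum(gb$converted) else NA
  list(conversion_change_pct = 100 * (rate_b - rate_a) / rate_a,
       cpa_change_pct = if (cpa_ok) 100 * (cpa_b - cpa_a) / cpa_a else NA,
       conversion_rate_a = rate_a, conversion_rate_b = rate_b,
       cpa_a = cpa_a, cpa_b = cpa_b, cpa_defined = cpa_ok)
}
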
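#' Cohort configuration for the synthetic-log simulator
#'
#' Describes the simulated cohort. Every user emits at least one search on
#' each of `days_per_user` consecutive calendar days (so calendar days and
#' search days coincide in the simulator), patients then visit one facility
#' on the following day, ending in a geofence dwell of at least 900 seconds.
#' Patient behaviour escalates over the final `signal_onset_day` search days
#' before the visit as linear ramps in four rate parameters, scaled by the
#' user's latent risk:
#'
#' * `health_rate`: multiplier on the per-search probability of a
#'   health-related search (default 3),
#' * `interval`: within-day shortening factor of intervals between
#'   consecutive health searches (default 3; intervals shrink to 1/3),
#' * `specificity`: drift towards deeper, more specific lexicon terms
#'   (default 3),
#' * `location`: multiplier on the probability that a search is made near a
#'   health-category landmark (default 4).
#'
#' Setting every multiplier to 1 yields the null world in which patients and
#' controls are statistically indistinguishable before the visit day.
#'
#' @param n_patients,n_controls cohort sizes
#' @param days_per_user search days per user before the endpoint (>= 42)
#' @param signal_onset_day days before the visit at which escalation starts
#' @param effect_sizes named list of the four multipliers described above
#' @param baseline_searches_per_day mean searches per user per day (>= 1)
#' @param base_health_rate baseline probability a search is health-related
#' @param base_location_rate baseline probability a search is made at a
#'   health landmark
#' @param start_date epoch seconds of the first simulated day
#' @param seed integer seed
#' @return a `cohort_config` list
#' @export
cohort_config <- function(n_patients = 500L,
                          n_controls = 500L,
                          days_per_user = 60L,
                          signal_onset_day = 15L,
                          effect_sizes = list(health_rate = 3,
                                              interval = 3,
                                              specificity = 3,
                                              location = 4),
                          baseline_searches_per_day = 4,
                          base_health_rate = 0.12,
                          base_location_rate = 0.05,
                          start_date = 1425168000,
                          seed = 1L) {
  if (days_per_user < 42)
    stop("days_per_user must be >= 42", call. = FALSE)
  rates <- c(baseline_searches_per_day, base_health_rate, base_location_rate,
             unlist(effect_sizes))
  if (any(rates <= 0)) stop("all rates must be > 0", call. = FALSE)
  stopifnot(all(c("health_rate", "interval", "specificity", "location") %in%
                  names(effect_sizes)))
  cfg <- list(n_patients = as.integer(n_patients),
              n_controls = as.integer(n_controls),
              days_per_user = as.integer(days_per_user),
              signal_onset_day = as.integer(signal_onset_day),
              effect_sizes = effect_sizes,
              baseline_searches_per_day = baseline_searches_per_day,
              base_health_rate = base_health_rate,
              base_location_rate = base_location_rate,
              start_date = start_date,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

# per-day escalation multiplier: linear ramp from 1 to 1 + (e-1)*risk_weight
# over the final signal_onset_day days; identically 1 off the ramp
ramp_multiplier <- function(ramp, effect, risk_weight) {
  1 + ramp * (effect - 1) * risk_weight
}

# generate one user's pre-endpoint search stream; returns a data.table
.simulate_user_stream <- function(uid, is_patient, risk, world, cfg) {
  D <- cfg$days_per_user
  ext <- world$config$map_extent
  e <- cfg$effect_sizes
  day0 <- floor(cfg$start_date / SECONDS_PER_DAY) + sample.int(8L, 1L) - 1L
  dates <- day0 + seq_len(D) - 1L

  home_lat <- runif(1, ext[["lat_min"]], ext[["lat_max"]])
  home_lon <- runif(1, ext[["lon_min"]], ext[["lon_max"]])

  # escalation ramp: 0 off-signal, rising linearly to 1 on the visit eve
  days_to_end <- D - seq_len(D)            # 0 on the last pre-visit day
  ramp <- if (is_patient)
    pmax(0, (cfg$signal_onset_day - days_to_end) / cfg$signal_onset_day)
  else rep(0, D)
  risk_w <- risk  # latent risk scales the escalation magnitude

  n_s <- 1L + rpois(D, max(cfg$baseline_searches_per_day - 1, 0.1))
  N <- sum(n_s)
  day_id <- rep(seq_len(D), n_s)

  m_rate <- ramp_multiplier(ramp, e$health_rate, risk_w)
  m_int <- ramp_multiplier(ramp, e$interval, risk_w)
  m_spec <- ramp_multiplier(ramp, e$specificity, risk_w)
  m_loc <- ramp_multiplier(ramp, e$location, risk_w)

  p_h <- pmin(0.85, cfg$base_health_rate * m_rate)
  is_health <- runif(N) < p_h[day_id]

  # timestamps: non-health searches uniform over the waking day; health
  # searches form a within-day cluster whose consecutive intervals shrink by
  # the factor 1/m_int (the interval-reduction signal)
  ts <- dates[day_id] * SECONDS_PER_DAY + runif(N, 8 * 3600, 22 * 3600)
  h_idx <- which(is_health)
  if (length(h_idx)) {
    h_day <- day_id[h_idx]
    ord <- order(h_day)
    h_idx <- h_idx[ord]
    h_day <- h_day[ord]
    k <- sequence(tabulate(h_day, nbins = D)[unique(h_day)])
    shrink <- (1 / m_int[h_day])^(k - 1L)
    delta <- 1800 * shrink * exp(rnorm(length(h_idx), 0, 0.3))
    start_u <- runif(D, 8 * 3600, 16 * 3600)
    within <- stats::ave(delta, h_day, FUN = cumsum)
    ts[h_idx] <- dates[h_day] * SECONDS_PER_DAY + start_u[h_day] + within
  }

  # locations: home jitter, or a (non-facility) health landmark visit
  lat <- home_lat + rnorm(N, 0, 0.004)
  lon <- home_lon + rnorm(N, 0, 0.004)
  p_loc <- pmin(0.5, cfg$base_location_rate * m_loc)
  at_lm <- runif(N) < p_loc[day_id]
  hl <- world$landmarks[world$landmarks$category == "health" &
                          !world$landmarks$is_facility, ]
  if (any(at_lm) && nrow(hl)) {
    pick <- sample.int(nrow(hl), sum(at_lm), replace = TRUE)
    lat[at_lm] <- hl$lat[pick] + rnorm(sum(at_lm), 0, 2e-4)
    lon[at_lm] <- hl$lon[pick] + rnorm(sum(at_lm), 0, 2e-4)
  }

  data.table::data.table(
    user_id = uid, ts = ts, lat = lat, lon = lon,
    is_health = is_health, day_id = day_id,
    beta = log(m_spec)[day_id]  # specificity-drift strength per search
  )
}

#' Generate synthetic user search streams with ground truth
#'
#' Patients emit searches whose health-token rate, inter-search intervals,
#' token specificity and health-landmark proximity escalate over the final
#' `signal_onset_day` days, ending in a geofence dwell of 1200 s at one
#' facility on the visit day. Controls emit stationary baseline streams and
#' never dwell inside any facility geofence. Latent risk scales the
#' escalation magnitude.
#'
#' @param world a [generate_world()] result
#' @param config a [cohort_config()]
#' @return list with `records` (user_id, ts, lat, lon, tokens; time-sorted
#'   per user) and `truth` (user_id, class, latent_risk, first_visit_time,
#'   visit_type, facility_id, n_days)
#' @export
generate_users <- function(world, config = cohort_config()) {
  stopifnot(inherits(world, "geoseek_world"), inherits(config, "cohort_config"))
  lex <- world$lexicon

  with_seed(config$seed, {
    n_p <- config$n_patients
    n_c <- config$n_controls
    ids <- sprintf("u%05d", seq_len(n_p + n_c))
    cls <- rep(c("patient", "control"), c(n_p, n_c))
    risk <- ifelse(cls == "patient", runif(n_p + n_c, 0.5, 1),
                   runif(n_p + n_c, 0, 0.5))
    fac <- world$facilities
    fac_id <- ifelse(cls == "patient",
                     fac$facility_id[(seq_len(n_p + n_c) - 1L) %%
                                       nrow(fac) + 1L], NA_character_)

    streams <- vector("list", n_p + n_c)
    visit_time <- rep(NA_real_, n_p + n_c)
    for (i in seq_len(n_p + n_c)) {
      st <- .simulate_user_stream(ids[i], cls[i] == "patient", risk[i],
                                  world, config)
      if (cls[i] == "patient") {
        f <- fac[fac$facility_id == fac_id[i], ]
        visit_date <- floor(max(st$ts) / SECONDS_PER_DAY) + 1L
        t0 <- visit_date * SECONDS_PER_DAY + 9 * 3600
        visit_time[i] <- t0
        dwell <- data.table::data.table(
          user_id = ids[i],
          ts = t0 + c(0, 600, 1200),
          lat = f$lat + rnorm(3, 0, 1e-4),
          lon = f$lon + rnorm(3, 0, 1e-4),
          is_health = TRUE, day_id = NA_integer_, beta = 0.5
        )
        st <- rbind(st, dwell)
      }
      streams[[i]] <- st
    }
    rec <- data.table::rbindlist(streams)

    # keep non-visit searches out of every facility geofence (controls must
    # never dwell; patients must have exactly one first visit)
    for (pass in 1:3) {
      dmin <- rep(Inf, nrow(rec))
      for (j in seq_len(nrow(fac))) {
        dmin <- pmin(dmin, haversine_distance(rec$lat, rec$lon,
                                              fac$lat[j], fac$lon[j]))
      }
      bad <- dmin < 220 & !is.na(rec$day_id)
      if (!any(bad)) break
      rec$lat[bad] <- rec$lat[bad] + 0.005
    }

    rec$tokens <- .draw_tokens(rec$is_health, rec$beta, lex)
    data.table::setorder(rec, user_id, ts)
    rec <- rec[, c("user_id", "ts", "lat", "lon", "tokens")]

    truth <- data.table::data.table(
      user_id = ids, class = cls, latent_risk = risk,
      first_visit_time = visit_time,
      visit_type = ifelse(cls == "patient",
                          fac$specialty[match(fac_id, fac$facility_id)],
                          NA_character_),
      facility_id = fac_id,
      n_days = config$days_per_user
    )
    list(records = rec, truth = truth)
  })
}

# Draw search text as a bag of lexicon terms: every search gets Zipf filler
# tokens (general-branch terms plus the mislabeled device terms, which are
# truly non-medical words); health searches add 1-2 medical terms sampled
# with weight own_count * exp(beta * depth), so beta > 0 drifts sampling
# towards deeper (more specific, higher-IC) concepts.
.draw_tokens <- function(is_health, beta, lex) {
  labs <- lex$term_labels
  filler_vocab <- labs$term[!labs$health]
  med_vocab <- labs$term[labs$health]
  cinfo <- lex$concepts
  med_concepts <- lex$terms$concept[match(med_vocab, lex$terms$term)]
  med_depth <- cinfo$depth[match(med_concepts, cinfo$concept)]
  med_own <- cinfo$own_count[match(med_concepts, cinfo$concept)]

  N <- length(is_health)
  zipf <- 1 / seq_along(filler_vocab)
  n_fill <- ifelse(is_health, sample(1:2, N, replace = TRUE),
                   sample(1:4, N, replace = TRUE, prob = c(.35, .35, .2, .1)))
  n_med <- ifelse(is_health, 1L + rbinom(N, 1L, 0.5), 0L)

  fill_draws <- sample(filler_vocab, sum(n_fill), replace = TRUE, prob = zipf)
  fill_dt <- data.table::data.table(id = rep(seq_len(N), n_fill),
                                    token = fill_draws)

  med_dt <- NULL
  hi <- which(n_med > 0L)
  if (length(hi)) {
    b <- round(beta[hi] / 0.05) * 0.05   # quantize drift for batched sampling
    med_rows <- vector("list", length(unique(b)))
    ub <- sort(unique(b))
    for (k in seq_along(ub)) {
      sel <- hi[b == ub[k]]
      w <- med_own * exp(ub[k] * med_depth)
      draws <- sample(med_vocab, sum(n_med[sel]), replace = TRUE,
                      prob = w / sum(w))
      med_rows[[k]] <- data.table::data.table(
        id = rep(sel, n_med[sel]), token = draws)
    }
    med_dt <- data.table::rbindlist(med_rows)
  }

  all_dt <- data.table::rbindlist(list(fill_dt, med_dt))
  data.table::setorder(all_dt, id)
  out <- all_dt[, .(tokens = paste(token, collapse = " ")), by = "id"]
  res <- character(N)
  res[out$id] <- out$tokens
  res
}

#' Generate an ad-impression stream with risk-tied conversions
#'
#' Each impression carries a user, a facility, a show time and a lognormal
#' cost. With probability `conv_fun(latent_risk)` the impression is followed
#' by a visit to the same facility within `lookahead_days`, so the
#' probability of conversion is an increasing function of latent risk
#' whenever `conv_fun` is increasing.
#'
#' @param truth ground-truth table from [generate_users()]
#' @param world a `geoseek_world`
#' @param n_impressions number of impressions to draw (0 allowed)
#' @param conv_fun probability of a post-impression visit as a function of
#'   latent risk in \[0, 1\]
#' @param lookahead_days horizon within which the induced visit occurs
#' @param period_start,period_days epoch start and length of the show period
#' @param cost_meanlog,cost_sdlog lognormal cost parameters
#' @param seed integer seed
#' @return list with `impressions` (user_id, facility_id, shown_time, cost)
#'   and `visits` (user_id, facility_id, entry_time)
#' @export
generate_ad_stream <- function(truth, world, n_impressions = 5000L,
                               conv_fun = function(r) 0.02 + 0.25 * r,
                               lookahead_days = 14,
                               period_start = 1425168000,
                               period_days = 60,
                               cost_meanlog = log(2), cost_sdlog = 0.5,
                               seed = 1L) {
  stopifnot(is.function(conv_fun))
  empty <- list(
    impressions = data.table::data.table(
      user_id = character(), facility_id = character(),
      shown_time = numeric(), cost = numeric()),
    visits = data.table::data.table(
      user_id = character(), facility_id = character(),
      entry_time = numeric()))
  if (n_impressions == 0L) return(empty)

  with_seed(seed, {
    ui <- sample.int(nrow(truth), n_impressions, replace = TRUE)
    fi <- sample.int(nrow(world$facilities), n_impressions, replace = TRUE)
    imp <- data.table::data.table(
      user_id = truth$user_id[ui],
      facility_id = world$facilities$facility_id[fi],
      shown_time = period_start +
        runif(n_impressions, 0, period_days * SECONDS_PER_DAY),
      cost = rlnorm(n_impressions, cost_meanlog, cost_sdlog)
    )
    p <- conv_fun(truth$latent_risk[ui])
    if (any(p < 0 | p > 1)) stop("conv_fun must map into [0, 1]",
                                 call. = FALSE)
    hit <- runif(n_impressions) < p
    visits <- data.table::data.table(
      user_id = imp$user_id[hit],
      facility_id = imp$facility_id[hit],
      entry_time = imp$shown_time[hit] +
        runif(sum(hit), 0.25, lookahead_days - 0.25) * SECONDS_PER_DAY
    )
    list(impressions = imp, visits = visits)
  })
}

#' Write / read search logs as tab-separated text
#'
#' Columns: user_id, ISO-8601 UTC timestamp, lat, lon, space-joined tokens.
#'
#' @param records records table from [generate_users()]
#' @param path file path
#' @return `read_search_logs` returns a records `data.table`
#' @export
write_search_logs <- function(records, path) {
  out <- data.table::data.table(
    user_id = records$user_id,
    timestamp = format(as.POSIXct(records$ts, origin = "1970-01-01",
                                  tz = "UTC"), "%Y-%m-%dT%H:%M:%OS3Z"),
    lat = records$lat, lon = records$lon, tokens = records$tokens
  )
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_search_logs
#' @export
read_search_logs <- function(path) {
  x <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("user_id", "timestamp", "tokens")))
  x$ts <- as.numeric(as.POSIXct(x$timestamp, tz = "UTC",
                                format = "%Y-%m-%dT%H:%M:%OSZ"))
  data.table::setorder(x, user_id, ts)
  x[, c("user_id", "ts", "lat", "lon", "tokens")]
}
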
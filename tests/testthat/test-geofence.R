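test_that("haversine distance matches its printed and oracle values", {
  # one ten-thousandth of a degree of latitude is about 11 m
  expect_equal(round(haversine_distance(0, 0, 1e-4, 0)), 11)
  expect_equal(haversine_distance(35.5, 110.2, 35.5, 110.2), 0)

  # symmetric, nonnegative, and within 1e-6 relative of the spherical
  # law-of-cosines oracle on 1000 random pairs
  withr::with_seed(11, {
    la1 <- runif(1000, -80, 80); lo1 <- runif(1000, -179, 179)
    la2 <- la1 + runif(1000, -1, 1); lo2 <- lo1 + runif(1000, -1, 1)
  })
  d <- haversine_distance(la1, lo1, la2, lo2)
  d_rev <- haversine_distance(la2, lo2, la1, lo1)
  expect_equal(d, d_rev)
  expect_true(all(d >= 0))
  to_rad <- pi / 180
  oracle <- 6371000 * acos(pmin(1,
    sin(la1 * to_rad) * sin(la2 * to_rad) +
      cos(la1 * to_rad) * cos(la2 * to_rad) * cos((lo2 - lo1) * to_rad)))
  expect_lt(max(abs(d - oracle) / pmax(oracle, 1)), 1e-6)

  expect_error(haversine_distance(91, 0, 0, 0), "latitude")
})

test_that("visit detection applies the run and dwell rules", {
  fac <- data.table::data.table(facility_id = "F1", lat = 30, lon = 120)
  near <- 30 + 50 / 111194.9  # ~50 m north of the facility

  # three searches at ~50 m spanning 1000 s: one event, dwell 1000 s
  r <- make_records(c(0, 500, 1000), lat = near, lon = 120)
  ev <- detect_facility_visits(r, fac)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$dwell_s, 1000)
  expect_equal(ev$n_searches_in_fence, 3L)
  expect_equal(ev$facility_id, "F1")

  # span of 600 s fails the 900 s dwell filter
  r2 <- make_records(c(0, 600), lat = near, lon = 120)
  expect_equal(nrow(detect_facility_visits(r2, fac)), 0)

  # everything 500 m away: outside the geofence
  far <- 30 + 500 / 111194.9
  r3 <- make_records(c(0, 500, 1000, 2000), lat = far, lon = 120)
  expect_equal(nrow(detect_facility_visits(r3, fac)), 0)

  # a >6 h gap breaks the run into two sub-dwell pieces
  r4 <- make_records(c(0, 1000, 30000, 30400), lat = near, lon = 120)
  ev4 <- detect_facility_visits(r4, fac)
  expect_equal(nrow(ev4), 1)   # only the first piece reaches 900 s
  expect_equal(ev4$dwell_s, 1000)

  # an out-of-fence search in between breaks the run
  r5 <- rbind(make_records(c(0, 500), lat = near, lon = 120),
              make_records(700, lat = far, lon = 120),
              make_records(c(1000, 1950), lat = near, lon = 120))
  ev5 <- detect_facility_visits(r5, fac)
  expect_equal(nrow(ev5), 1)
  expect_equal(ev5$dwell_s, 950)

  expect_error(detect_facility_visits(r, fac[0, ]), "empty")

  # shuffling then sorting the log leaves events identical
  fx <- fx_small()
  rec <- fx$sim$records
  shuf <- rec[sample.int(nrow(rec)), ]
  ev_a <- detect_facility_visits(rec, fx$world$facilities, fx$policy)
  ev_b <- detect_facility_visits(shuf, fx$world$facilities, fx$policy)
  data.table::setorder(ev_a, user_id, entry_time)
  data.table::setorder(ev_b, user_id, entry_time)
  expect_equal(ev_a, ev_b)
})

test_that("cohort filters implement the four inclusion/exclusion predicates", {
  fac <- data.table::data.table(facility_id = c("F1", "F2", "F3", "F4",
                                                "F5", "F6"),
                                lat = 30 + 0:5 * 0.1, lon = 120)
  near <- function(i, dt) make_records(dt, lat = fac$lat[i] + 20 / 111194.9,
                                       lon = 120, user = "u1")
  day <- 86400

  # qualifying user: one 1000 s visit and 45 distinct prior search days
  ok <- rbind(
    make_records(day * (1:45) + 3600, lat = 31.9, lon = 121, user = "u1"),
    near(1, day * 46 + c(0, 500, 1000)))
  vis <- detect_facility_visits(ok, fac)
  kept <- apply_cohort_filters(vis, ok, fac)
  expect_equal(kept$user_id, "u1")
  expect_equal(kept$visit_time, day * 46)

  # 16 proximal searches in one calendar month: excluded
  too_many <- rbind(ok, near(1, day * 40 + 100 * (1:15)))
  vis2 <- detect_facility_visits(too_many, fac)
  expect_equal(nrow(apply_cohort_filters(vis2, too_many, fac)), 0)

  # proximal to 6 distinct facilities in one month: excluded
  six <- rbind(ok, data.table::rbindlist(
    lapply(2:6, function(i) near(i, day * 40 + i * 4000))))
  vis3 <- detect_facility_visits(six, fac)
  expect_equal(nrow(apply_cohort_filters(vis3, six, fac)), 0)

  # fewer than 42 prior search days: excluded
  short <- rbind(
    make_records(day * (1:30) + 3600, lat = 31.9, lon = 121, user = "u1"),
    near(1, day * 31 + c(0, 500, 1000)))
  vis4 <- detect_facility_visits(short, fac)
  expect_equal(nrow(apply_cohort_filters(vis4, short, fac)), 0)

  # the retained set equals the intersection of independently evaluated
  # predicates on the small synthetic cohort (filters commute)
  fx <- fx_small()
  rec <- fx$sim$records
  viss <- detect_facility_visits(rec, fx$world$facilities, fx$policy)
  kept2 <- apply_cohort_filters(viss, rec, fx$world$facilities, fx$policy)
  # independent oracle: per-user predicate evaluation
  prox <- rec[!is.na(geoseek:::.nearest_fence(rec, fx$world$facilities,
                                              fx$policy)), ]
  prox$fence <- geoseek:::.nearest_fence(prox, fx$world$facilities,
                                         fx$policy)
  prox$month <- format(as.POSIXct(prox$ts, origin = "1970-01-01",
                                  tz = "UTC"), "%Y-%m")
  users <- unique(viss$user_id)
  oracle_keep <- Filter(function(u) {
    pu <- prox[prox$user_id == u, ]
    mc <- tapply(pu$ts, pu$month, length)
    mf <- tapply(pu$fence, pu$month, function(x) length(unique(x)))
    first_visit <- min(viss$entry_time[viss$user_id == u])
    before <- rec[rec$user_id == u &
                    rec$ts < floor(first_visit / 86400) * 86400, ]
    n_days <- length(unique(floor(before$ts / 86400)))
    all(mc <= 15) && all(mf <= 5) && n_days >= 42
  }, users)
  expect_setequal(kept2$user_id, oracle_keep)
})

test_that("control sampling matches on search-day counts", {
  day <- 86400
  mk <- function(u, ndays, lat = 45) make_records(day * seq_len(ndays) + 10,
                                                  lat = lat, lon = 50,
                                                  user = u)
  fac <- data.table::data.table(facility_id = "F1", lat = 30, lon = 120)
  patients <- data.table::data.table(user_id = c("p1", "p2"),
                                     endpoint_time = c(day * 51, day * 61),
                                     visit_time = c(day * 51, day * 61))
  rec <- rbind(mk("p1", 50), mk("p2", 60), mk("c1", 50), mk("c2", 60),
               mk("c3", 55))
  vis <- data.table::data.table(user_id = character(),
                                facility_id = character(),
                                entry_time = numeric(), dwell_s = numeric(),
                                n_searches_in_fence = integer())

  ctl <- sample_controls(rec, vis, patients, seed = 1)
  expect_setequal(ctl$user_id, c("c1", "c2"))
  expect_true(all(ctl$matched_exactly))
  expect_equal(ctl$n_days[match(c("p1", "p2"), ctl$matched_patient)],
               c(50, 60))

  # nearest-count fallback when no exact match exists, and it is flagged
  rec2 <- rbind(mk("p1", 50), mk("c4", 49), mk("c5", 30))
  pat1 <- patients[1, ]
  expect_message(ctl2 <- sample_controls(rec2, vis, pat1, seed = 1),
                 "nearest")
  expect_equal(ctl2$user_id, "c4")
  expect_false(ctl2$matched_exactly)

  # deterministic under a fixed seed
  ctl_a <- sample_controls(rec, vis, patients, seed = 5)
  ctl_b <- sample_controls(rec, vis, patients, seed = 5)
  expect_identical(ctl_a, ctl_b)

  # pool smaller than requested: error naming the shortfall
  expect_error(sample_controls(mk("p1", 50), vis, patients, seed = 1),
               "short by")
})
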